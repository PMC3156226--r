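# Walks ------------------------------------------------------------------
#
# A walk is an ordered set of inner edges joined at shared terminal reads
# (crossing one real edge, or one reversal vertex for cycle-branch arcs).
# Steps are (inner_id, enter_vertex): the vertex through which the walk
# enters each unique path.

# Reverse a walk: same edges in reverse order, each entered from its other
# vertex.
rev_walk_vertices <- function(steps, inner_tbl) {
  other <- map_chr(seq_len(nrow(steps)), function(j) {
    row <- inner_tbl[inner_tbl$inner_id == steps$inner_id[j], ]
    if (steps$enter_vertex[j] == row$v1) row$v2 else row$v1
  })
  rev(other)
}

# Compose global read placements along a walk.
walk_placements <- function(pg_inner, steps, lens) {
  placements <- NULL
  prev_exit <- NULL
  for (j in seq_len(nrow(steps))) {
    row <- pg_inner[pg_inner$inner_id == steps$inner_id[j], ]
    assert_that(nrow(row) == 1L, "walk cites unknown inner edge")
    flip <- !is.na(steps$enter_vertex[j]) && steps$enter_vertex[j] == row$v2
    reads <- row$reads[[1]]; offs <- row$offsets[[1]]; oris <- row$orients[[1]]
    span <- row$length
    if (flip) {
      offs <- span - (offs + unname(lens[reads]))
      oris <- flip_orient(oris)
    }
    if (j == 1L) {
      base <- 0
    } else {
      r <- vertex_read(steps$enter_vertex[j])
      # global placement of the junction read from the previous step
      gp <- placements[placements$read == r, , drop = FALSE]
      assert_that(nrow(gp) >= 1L, "walk junction read missing from layout")
      gp <- gp[nrow(gp), , drop = FALSE]
      # the junction read is the terminal at the entering side: the first
      # read when entering at v1, the last when entering at v2 (flip)
      k <- if (flip) which(reads == r)[sum(reads == r)] else which(reads == r)[1]
      assert_that(length(k) == 1L && !is.na(k), "junction read absent from path")
      if (oris[k] != gp$orient) {
        # orientation bookkeeping must agree; flip as a defensive fallback
        warn("walk orientation mismatch at junction; flipping path")
        offs <- span - (offs + unname(lens[reads]))
        oris <- flip_orient(oris)
        k <- which(reads == r)[1]
      }
      base <- gp$offset - offs[k]
    }
    step_pl <- tibble(read = reads, offset = base + offs, orient = oris,
                      step = j)
    placements <- bind_rows(placements, step_pl)
  }
  # collapse duplicate placements of junction reads (same read, same spot)
  placements <- distinct(placements, .data$read, .data$offset, .data$orient,
                         .keep_all = TRUE)
  placements$offset <- placements$offset - min(placements$offset)
  placements
}

# Majority-vote consensus over placed reads (optionally adding contained
# reads through their exemplar placements).
consensus_from_placements <- function(placements, graph, config = NULL,
                                      with_contained = TRUE) {
  reads <- graph$reads
  lens <- setNames(nchar(reads$seq), reads$id)
  seqs <- setNames(reads$seq, reads$id)
  quals <- setNames(reads$qual, reads$id)

  if (with_contained && nrow(graph$exemplar_of)) {
    ex <- graph$exemplar_of
    extra <- inner_join(ex, placements, by = c("exemplar" = "read"),
                        relationship = "many-to-many")
    if (nrow(extra)) {
      lex <- unname(lens[extra$exemplar]); lc <- unname(lens[extra$read])
      g_off <- ifelse(extra$orient.y == "F",
                      extra$offset.y + extra$offset.x,
                      extra$offset.y + lex - extra$offset.x - lc)
      placements <- bind_rows(placements,
                              tibble(read = extra$read, offset = g_off,
                                     orient = compose_orient(extra$orient.y,
                                                             extra$orient.x),
                                     step = NA_integer_))
    }
  }

  span <- max(placements$offset + unname(lens[placements$read]))
  counts <- matrix(0L, nrow = 5L, ncol = span)     # A C G T N
  qsum <- matrix(0, nrow = 5L, ncol = span)
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("N")] <- 5L
  for (i in seq_len(nrow(placements))) {
    id <- placements$read[i]
    s <- seqs[[id]]
    if (placements$orient[i] == "R") s <- revcomp(s)
    b <- code[utf8ToInt(s)]
    cols <- placements$offset[i] + seq_len(nchar(s))
    ix <- cbind(b, cols)
    counts[ix] <- counts[ix] + 1L
    q <- quals[[id]]
    if (is.null(q)) q <- rep(30, nchar(s))
    if (placements$orient[i] == "R") q <- rev(q)
    qsum[ix] <- qsum[ix] + q
  }
  support <- colSums(counts)
  if (any(support == 0L)) {
    # overlap-driven layouts cannot leave uncovered columns; a gap means the
    # walk was inconsistent -- report loudly
    abort("zero-coverage column in consensus layout")
  }
  # majority base; ties by summed quality, then base order (N last)
  pref <- c(5L, 4L, 3L, 2L, 1L)  # preference rank: A > C > G > T > N
  best <- max.col(t(counts) * 100000 + t(qsum) * 10 + matrix(pref, span, 5L, byrow = TRUE),
                  ties.method = "first")
  seq <- intToUtf8(c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"),
                     utf8ToInt("T"), utf8ToInt("N"))[best], multiple = FALSE)
  list(seq = seq, support = as.integer(support), placements = placements)
}

# Consensus sequence of a single inner edge (no contained reads), used for
# cycle-branch similarity tests.
inner_consensus <- function(pg, inner_id, config = NULL) {
  row <- pg$inner[pg$inner$inner_id == inner_id, ]
  pl <- tibble(read = row$reads[[1]], offset = row$offsets[[1]],
               orient = row$orients[[1]], step = 1L)
  consensus_from_placements(pl, pg$graph, config, with_contained = FALSE)$seq
}

# Consensus of an arc/walk given as steps.
walk_consensus <- function(pg_like, steps, graph, config = NULL,
                           with_contained = TRUE) {
  lens <- setNames(graph$vertices$length, graph$vertices$id)
  pl <- walk_placements(pg_like, steps, lens)
  consensus_from_placements(pl, graph, config, with_contained = with_contained)
}

#' Extract the final longest paths from a spanning subgraph
#'
#' From every leaf of the (directed-cycle-free) spanning subgraph the longest
#' orientation-consistent path is computed; the longest paths are then
#' re-computed from the end-vertices of those paths (once by default, to a
#' fixpoint with `longest_path_fixpoint`). Path length is the consensus
#' base-pair length estimate.
#'
#' @param subgraph A `spanning_subgraph` from [build_spanning_subgraph()].
#' @return A list of walks (tibbles of `inner_id`, `enter_vertex`), one per
#'   candidate path.
#' @export
extract_longest_paths <- function(subgraph) {
  tg <- traversal_edges(subgraph)
  inner <- subgraph$inner
  lens_by_id <- setNames(inner$length, inner$inner_id)

  # adjacency
  vs <- unique(c(tg$v1, tg$v2))
  adj <- split(rep(seq_len(nrow(tg)), 2L), c(tg$v1, tg$v2))
  deg <- lengths(adj)
  leaves <- names(deg)[deg == 1L]
  if (!nrow(tg)) return(list())

  junction_len <- function(v) {
    l <- subgraph$read_lens[vertex_read(v)]
    if (is.na(l)) 0L else unname(l)
  }

  best_from <- function(v, used = character(0)) {
    # returns list(len, steps) of the best alternating walk starting at
    # vertex v, where the next move must be an inner edge
    eids <- adj[[v]]
    best <- list(len = 0, steps = NULL)
    for (i in eids) {
      e <- tg[i, ]
      if (e$type != "inner" || e$eid %in% used) next
      w <- if (e$v1 == v) e$v2 else e$v1
      # cross the real edge at w, if one is selected
      nxt <- NULL
      for (jj in adj[[w]]) {
        e2 <- tg[jj, ]
        if (e2$type == "real" && (e2$v1 == w || e2$v2 == w)) { nxt <- e2; break }
      }
      sub_best <- list(len = 0, steps = NULL)
      if (!is.null(nxt)) {
        w2 <- if (nxt$v1 == w) nxt$v2 else nxt$v1
        sub_best <- best_from(w2, c(used, e$eid))
      }
      cand_len <- lens_by_id[[e$eid]] + sub_best$len -
        (if (!is.null(sub_best$steps)) junction_len(w) else 0)
      if (cand_len > best$len ||
          (cand_len == best$len && !is.null(best$steps) &&
             e$eid < best$steps$inner_id[1])) {
        best <- list(len = cand_len,
                     steps = bind_rows(tibble(inner_id = e$eid, enter_vertex = v),
                                       sub_best$steps))
      }
    }
    best
  }

  walk_ends <- function(steps) {
    first <- steps[1, ]; lastr <- steps[nrow(steps), ]
    row1 <- inner[inner$inner_id == first$inner_id, ]
    rown <- inner[inner$inner_id == lastr$inner_id, ]
    start_v <- first$enter_vertex
    end_v <- if (lastr$enter_vertex == rown$v1) rown$v2 else rown$v1
    c(start_v, end_v)
  }

  walks <- list()
  seen_keys <- character(0)
  add_walk <- function(w) {
    if (is.null(w$steps)) return(invisible(NULL))
    key <- paste(sort(w$steps$inner_id), collapse = ",")
    if (!key %in% seen_keys) {
      seen_keys <<- c(seen_keys, key)
      walks[[length(walks) + 1L]] <<- w
    }
    invisible(NULL)
  }
  for (v in sort(leaves)) add_walk(best_from(v))
  # re-iterate from the end-vertices of the found paths
  repeat {
    ends <- unique(unlist(map(walks, function(w) walk_ends(w$steps))))
    n_before <- length(walks)
    for (v in sort(ends)) add_walk(best_from(v))
    if (length(walks) == n_before || !isTRUE(subgraph$config$longest_path_fixpoint))
      break
  }
  # inner edges not reachable from any leaf (their vertices sit at
  # unresolved junctions) still carry sequence: walk each one, extended as
  # far as the alternating rule allows on both sides
  cross_real <- function(w) {
    for (jj in adj[[w]] %||% integer(0)) {
      e2 <- tg[jj, ]
      if (e2$type == "real") return(if (e2$v1 == w) e2$v2 else e2$v1)
    }
    NULL
  }
  used <- unique(unlist(map(walks, function(w) w$steps$inner_id)))
  comp_missing <- setdiff(tg$eid[tg$type == "inner"], used)
  for (eid in comp_missing) {
    e <- tg[tg$eid == eid, ][1, ]
    row <- inner[inner$inner_id == eid, ]
    # forward continuation beyond v2, backward beyond v1
    fwd <- list(len = 0, steps = NULL)
    w2 <- cross_real(e$v2)
    if (!is.null(w2)) fwd <- best_from(w2, used = eid)
    bwd <- list(len = 0, steps = NULL)
    w1 <- cross_real(e$v1)
    if (!is.null(w1)) bwd <- best_from(w1, used = c(eid, fwd$steps$inner_id))
    steps <- bind_rows(
      if (!is.null(bwd$steps))
        tibble(inner_id = rev(bwd$steps$inner_id),
               enter_vertex = rev_walk_vertices(bwd$steps, inner)),
      tibble(inner_id = eid, enter_vertex = e$v1),
      fwd$steps)
    add_walk(list(len = row$length + fwd$len + bwd$len, steps = steps))
  }
  walks
}

#' Keep only the longest path among paths sharing a subpath
#'
#' Paths sharing at least one inner edge are redundant; within any such group
#' only the longest survives (ties by first inner-edge id), so the retained
#' paths are pairwise inner-edge-disjoint.
#'
#' @param paths List of walks from [extract_longest_paths()].
#' @return The filtered list of walks.
#' @export
deduplicate_paths <- function(paths) {
  if (!length(paths)) return(paths)
  lens <- map_dbl(paths, function(w) w$len)
  firsts <- map_chr(paths, function(w) w$steps$inner_id[1])
  ord <- order(-lens, firsts)
  kept <- list()
  used <- character(0)
  for (i in ord) {
    ids <- paths[[i]]$steps$inner_id
    if (!length(intersect(ids, used))) {
      kept[[length(kept) + 1L]] <- paths[[i]]
      used <- c(used, ids)
    }
  }
  kept
}

#' Call the consensus contig for one path
#'
#' Reads of the path are laid out by their cumulative overlap offsets;
#' contained reads are placed through their containment alignment to the
#' exemplar; each column takes the majority base, ties broken by higher
#' summed Phred quality and then base order.
#'
#' @param path A walk (as returned by [extract_longest_paths()]).
#' @param subgraph The `spanning_subgraph` the walk lives in.
#' @param id Contig id.
#' @return A one-row contigs tibble (`id`, `seq`, `length`, `read_path` list,
#'   `support` list, `n_reads`).
#' @export
call_consensus <- function(path, subgraph, id = "ctg1") {
  graph <- subgraph$pg$graph
  cons <- walk_consensus(subgraph$inner, path$steps, graph,
                         subgraph$config, with_contained = TRUE)
  pl <- cons$placements[order(cons$placements$offset), ]
  tibble(id = id, seq = cons$seq, length = nchar(cons$seq),
         read_path = list(pl$read), support = list(cons$support),
         n_reads = nrow(pl))
}

# All contigs of a spanning subgraph.
contigs_from_subgraph <- function(subgraph, prefix = "ctg") {
  paths <- deduplicate_paths(extract_longest_paths(subgraph))
  if (!length(paths))
    return(tibble(id = character(0), seq = character(0), length = integer(0),
                  read_path = list(), support = list(), n_reads = integer(0)))
  out <- map(seq_along(paths), function(i)
    call_consensus(paths[[i]], subgraph, sprintf("%s%04d", prefix, i)))
  bind_rows(out)
}
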
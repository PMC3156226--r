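#' Transform a reduced overlap graph into a path graph
#'
#' Maximal unique (branch-free, orientation-consistent) paths of the overlap
#' graph are condensed: each becomes one *inner edge* whose two vertices are
#' the outer ends of the first and last read of the path (the read ends
#' facing away from the path body). Reads can terminate several unique paths;
#' a *real edge* is inserted between the two end-vertices of every read that
#' terminates at least two distinct unique paths, representing the passage
#' through that shared read. Isolated reads become single-read inner edges.
#'
#' @param graph An `overlap_graph` after [reduce_containments()] and
#'   [transitive_reduction()].
#' @return A `path_graph`: list with `vertices` (`vertex`, `read`, `end`),
#'   `inner` (one row per unique path, with read layout and consensus-length
#'   estimate), `real` (real edges), and the underlying `graph`.
#' @export
build_path_graph <- function(graph) {
  ov <- graph$edges[graph$edges$kind == "overlap", , drop = FALSE]
  act <- active_reads(graph)
  ov <- ov[ov$read_a %in% act & ov$read_b %in% act, , drop = FALSE]
  lens <- setNames(graph$vertices$length, graph$vertices$id)

  # degree per read end
  ends <- c(paste0(ov$read_a, "|", ov$end_a), paste0(ov$read_b, "|", ov$end_b))
  deg <- table(ends)
  deg_of <- function(read, end) {
    v <- deg[vertex_id(read, end)]
    if (is.na(v)) 0L else as.integer(v)
  }
  pass_through <- setNames(vapply(act, function(r)
    deg_of(r, "L") == 1L && deg_of(r, "R") == 1L, logical(1)), act)

  # adjacency: edge ids incident at each read end
  adj <- split(rep(ov$edge_id, 2L), ends)
  edge_by_id <- split(ov, ov$edge_id)
  end_at <- function(e, r) if (e$read_a == r) e$end_a else e$end_b
  other_read <- function(e, r) if (e$read_a == r) e$read_b else e$read_a

  visited <- new.env(parent = emptyenv())
  chains <- list()

  walk_from <- function(r0, e0) {
    # walk a unique path starting at terminal read r0 through edge e0
    reads <- r0
    eids <- integer(0)
    entry_end <- end_at(e0, r0)   # end of r0 the path body attaches to
    cur <- r0; e <- e0
    repeat {
      assign(as.character(e$edge_id), TRUE, envir = visited)
      nb <- other_read(e, cur)
      # a revisited pass-through read closes a pure cycle: the closing edge
      # is dropped (the cycle is broken deterministically); looping back to
      # a terminal read keeps the edge (the read ends the path a second
      # time)
      if (nb %in% reads && isTRUE(pass_through[[nb]])) break
      eids <- c(eids, e$edge_id)
      reads <- c(reads, nb)
      nb_in <- end_at(e, nb)
      if (!isTRUE(pass_through[[nb]])) break
      nxt_ids <- adj[[vertex_id(nb, other_end(nb_in))]]
      if (is.null(nxt_ids)) break
      nxt <- edge_by_id[[as.character(nxt_ids[1])]]
      if (exists(as.character(nxt$edge_id), envir = visited)) break  # cycle closed
      cur <- nb; e <- nxt
    }
    list(reads = reads, eids = eids, entry_end = entry_end)
  }

  # chains start at terminal (non-pass-through) reads ...
  terminals <- sort(names(pass_through)[!pass_through])
  for (r in terminals) {
    for (end in c("L", "R")) {
      for (eid in sort(adj[[vertex_id(r, end)]])) {
        if (exists(as.character(eid), envir = visited)) next
        chains[[length(chains) + 1L]] <-
          walk_from(r, edge_by_id[[as.character(eid)]])
      }
    }
  }
  # ... remaining unvisited edges lie on all-pass-through cycles: break each
  # at its lexicographically smallest read (deterministic rotation)
  left <- ov[!vapply(as.character(ov$edge_id), exists, logical(1),
                     envir = visited), , drop = FALSE]
  if (nrow(left)) {
    gcyc <- igraph::graph_from_data_frame(left[, c("read_a", "read_b")],
                                          directed = FALSE)
    memb <- igraph::components(gcyc)$membership
    for (cmp in unique(memb)) {
      members <- names(memb)[memb == cmp]
      r0 <- min(members)
      eids0 <- sort(c(left$edge_id[left$read_a == r0],
                      left$edge_id[left$read_b == r0]))
      chains[[length(chains) + 1L]] <-
        walk_from(r0, edge_by_id[[as.character(eids0[1])]])
    }
  }
  # isolated reads
  deg_tot <- table(c(ov$read_a, ov$read_b))
  isolated <- setdiff(act, names(deg_tot))
  for (r in isolated)
    chains[[length(chains) + 1L]] <- list(reads = r, eids = integer(0),
                                          entry_end = NA_character_)

  inner <- map(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    lay <- layout_chain(ch, edge_by_id, lens)
    n <- length(ch$reads)
    if (n == 1L) {
      v1 <- vertex_id(ch$reads[1], "L"); v2 <- vertex_id(ch$reads[1], "R")
    } else {
      e_first <- edge_by_id[[as.character(ch$eids[1])]]
      e_last <- edge_by_id[[as.character(ch$eids[length(ch$eids)])]]
      v1 <- vertex_id(ch$reads[1], other_end(end_at(e_first, ch$reads[1])))
      v2 <- vertex_id(ch$reads[n], other_end(end_at(e_last, ch$reads[n])))
      if (lay$flipped) { tmp <- v1; v1 <- v2; v2 <- tmp }
    }
    sub <- ov[ov$edge_id %in% ch$eids, , drop = FALSE]
    identity <- if (nrow(sub)) 1 - sum(sub$mismatches) / sum(sub$length) else 1
    tibble(inner_id = NA_character_, v1 = v1, v2 = v2,
           reads = list(lay$reads), orients = list(lay$orient),
           offsets = list(lay$offset), length = lay$span,
           identity = identity,
           coverage = sum(lens[ch$reads]) / lay$span,
           n_reads = n)
  })
  inner <- bind_rows(inner)
  if (nrow(inner)) {
    # canonical order and ids independent of traversal order
    key <- map_chr(inner$reads, function(r) paste(sort(c(r[1], r[length(r)])), collapse = "~"))
    inner <- inner[order(key, -inner$length, inner$v1, inner$v2), , drop = FALSE]
    inner$inner_id <- sprintf("P%04d", seq_len(nrow(inner)))
  } else {
    inner <- tibble(inner_id = character(0), v1 = character(0), v2 = character(0),
                    reads = list(), orients = list(), offsets = list(),
                    length = integer(0), identity = numeric(0),
                    coverage = numeric(0), n_reads = integer(0))
  }

  # reads terminating >= 2 distinct unique paths get a real edge
  term <- unlist(map(inner$reads, function(r)
    if (length(r) == 1L) r[1] else c(r[1], r[length(r)])))
  term_n <- table(term)
  real_reads <- sort(names(term_n)[term_n >= 2L])
  real <- tibble(real_id = if (length(real_reads))
                   sprintf("R%04d", seq_along(real_reads)) else character(0),
                 v1 = vertex_id(real_reads, "L"),
                 v2 = vertex_id(real_reads, "R"),
                 read = real_reads)

  verts <- unique(c(inner$v1, inner$v2, real$v1, real$v2))
  vertices <- tibble(vertex = verts, read = vertex_read(verts),
                     end = vertex_end(verts))

  structure(list(vertices = vertices, inner = inner, real = real,
                 graph = graph), class = "path_graph")
}

# Lay out the reads of one chain: compose placements along its edges and
# canonicalise (first offset zero; orientation fixed so the lexicographically
# smaller terminal read comes first on the forward strand).
layout_chain <- function(ch, edge_by_id, lens) {
  reads <- ch$reads
  n <- length(reads)
  off <- numeric(n); ori <- character(n)
  off[1] <- 0; ori[1] <- "F"
  for (i in seq_along(ch$eids)) {
    e <- edge_by_id[[as.character(ch$eids[i])]]
    la <- lens[[e$read_a]]; lb <- lens[[e$read_b]]
    if (e$read_a == reads[i]) {
      p <- place_b_from_a(off[i], ori[i], la, lb, e$diag, e$orient)
    } else {
      p <- place_a_from_b(off[i], ori[i], la, lb, e$diag, e$orient)
    }
    off[i + 1L] <- p$offset; ori[i + 1L] <- p$orient
  }
  off <- off - min(off)
  span <- max(off + lens[reads])
  # geometric convention: the walk's first read sits at the frame's left end
  # (ascending offsets along the walk), so that entering an inner edge at v1
  # always traverses the stored frame forward
  if (n >= 2L && off[1] > off[n]) {
    off <- span - (off + lens[reads])
    ori <- flip_orient(ori)
  }
  # deterministic canonical order: smaller terminal read id first
  flip <- reads[n] < reads[1]
  if (flip) {
    off <- rev(span - (off + lens[reads]))
    ori <- rev(flip_orient(ori))
    reads <- rev(reads)
  }
  if (n == 1L && ori[1] == "R") ori[1] <- "F"
  list(reads = reads, offset = as.integer(off), orient = ori,
       span = as.integer(span), flipped = flip)
}

# diagonal of the alignment with the roles of read_a/read_b swapped
swap_diag <- function(e, lens) {
  la <- lens[[e$read_a]]; lb <- lens[[e$read_b]]
  if (e$orient == "F") -e$diag else lb - la + e$diag
}

#' @export
print.path_graph <- function(x, ...) {
  cat(sprintf("<path_graph> %d vertices, %d inner edges (unique paths), %d real edges\n",
              nrow(x$vertices), nrow(x$inner), nrow(x$real)))
  invisible(x)
}
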
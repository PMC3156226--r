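# Spanning-subgraph layout ----------------------------------------------------
#
# Real edges of the path graph are considered greedily by score.  Candidates
# that would introduce a directed cycle (orientation-consistent, the
# signature of a repeat) are rejected and the cycle is cut open; undirected
# cycles (bubbles) are kept and marked when their two branch sequences are
# similar (sequencing error / SNP), rejected when dissimilar (false
# alignment).  Mate pairs can later re-link cut repeat branches, duplicating
# the repeat path.

#' Score a real edge of the path graph
#'
#' The score combines the mean alignment identity of the unique paths meeting
#' at the edge's read (quality term, 0-1) with their mean read coverage,
#' normalised at `coverage_target`:
#' `lambda * quality + (1 - lambda) * min(coverage / coverage_target, 1)`.
#'
#' @param edge One row of the path graph's `real` tibble (or a real-edge id).
#' @param path_graph A `path_graph`.
#' @param config An `asm_config`.
#' @return A one-row tibble with `quality_term`, `coverage_term`, `combined`.
#' @export
score_real_edge <- function(edge, path_graph, config = assembly_config()) {
  if (is.character(edge))
    edge <- path_graph$real[path_graph$real$real_id == edge, ]
  scores <- score_real_edges(path_graph, config)
  scores[scores$real_id == edge$real_id,
         c("real_id", "quality_term", "coverage_term", "combined")]
}

score_real_edges <- function(pg, config) {
  real <- pg$real
  if (!nrow(real))
    return(tibble(real_id = character(0), quality_term = numeric(0),
                  coverage_term = numeric(0), combined = numeric(0)))
  ctarget <- config$coverage_target %||% (2 * stats::median(pg$inner$coverage))
  if (!is.finite(ctarget) || ctarget <= 0) ctarget <- 1
  inc <- bind_rows(
    tibble(v = pg$inner$v1, identity = pg$inner$identity, coverage = pg$inner$coverage),
    tibble(v = pg$inner$v2, identity = pg$inner$identity, coverage = pg$inner$coverage))
  qual <- map_dbl(seq_len(nrow(real)), function(i) {
    x <- inc[inc$v %in% c(real$v1[i], real$v2[i]), ]
    if (!nrow(x)) 1 else mean(x$identity)
  })
  cov <- map_dbl(seq_len(nrow(real)), function(i) {
    x <- inc[inc$v %in% c(real$v1[i], real$v2[i]), ]
    if (!nrow(x)) 0 else mean(x$coverage)
  })
  tibble(real_id = real$real_id, quality_term = qual, coverage_term = cov,
         combined = config$lambda_score * qual +
           (1 - config$lambda_score) * pmin(cov / ctarget, 1))
}

# Edge view of the current subgraph (active inner edges + selected reals).
traversal_edges <- function(subgraph) {
  inner <- subgraph$inner[subgraph$inner$active, , drop = FALSE]
  bind_rows(
    tibble(eid = inner$inner_id, type = "inner", v1 = inner$v1, v2 = inner$v2),
    if (nrow(subgraph$real_selected))
      tibble(eid = subgraph$real_selected$real_id, type = "real",
             v1 = subgraph$real_selected$v1, v2 = subgraph$real_selected$v2)
  )
}

# BFS path between two vertices over an edge tibble; returns the ordered edge
# rows (with the vertex sequence) or NULL.
find_path <- function(edges, from, to, skip_eid = NULL) {
  if (!nrow(edges)) return(NULL)
  if (!is.null(skip_eid)) edges <- edges[edges$eid != skip_eid, , drop = FALSE]
  if (!nrow(edges)) return(NULL)
  adj <- split(rep(seq_len(nrow(edges)), 2L), c(edges$v1, edges$v2))
  if (is.null(adj[[from]])) return(NULL)
  prev_edge <- list(); prev_vert <- list()
  seen <- new.env(parent = emptyenv())
  assign(from, TRUE, envir = seen)
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (i in adj[[v]] %||% integer(0)) {
      w <- if (edges$v1[i] == v) edges$v2[i] else edges$v1[i]
      if (exists(w, envir = seen)) next
      assign(w, TRUE, envir = seen)
      prev_edge[[w]] <- i; prev_vert[[w]] <- v
      queue <- c(queue, w)
    }
  }
  if (!exists(to, envir = seen) || from == to) return(NULL)
  # backtrack
  path_i <- integer(0); verts <- to
  v <- to
  while (v != from) {
    path_i <- c(prev_edge[[v]], path_i)
    v <- prev_vert[[v]]
    verts <- c(v, verts)
  }
  out <- edges[path_i, , drop = FALSE]
  out$from <- verts[-length(verts)]
  out$to <- verts[-1]
  out
}

#' Classify a cycle of the path graph
#'
#' A cycle is *directed* when it can be traversed consistently with read
#' orientation: inner edges and real edges strictly alternate around it (every
#' junction passes through a read end to the read's other end). Otherwise the
#' cycle is undirected (it reverses direction at one or more vertices where
#' two unique paths meet head-on) and the global identity of its two branch
#' consensus sequences decides between `undirected_similar` (sequencing
#' error/SNP bubble) and `undirected_dissimilar` (false alignment).
#'
#' @param cycle Ordered edge tibble of the cycle (columns `eid`, `type`,
#'   `from`, `to`, circular order).
#' @param path_graph A `path_graph` (or `spanning_subgraph`) supplying inner
#'   edge layouts for branch consensus.
#' @param similarity Identity threshold for similar branches.
#' @return One of `"directed"`, `"undirected_similar"`,
#'   `"undirected_dissimilar"`.
#' @export
classify_cycle <- function(cycle, path_graph, similarity = 0.90) {
  n <- nrow(cycle)
  nxt <- c(2:n, 1L)
  reversal <- which(cycle$type == "inner" & cycle$type[nxt] == "inner")
  if (!length(reversal)) return("directed")
  if (length(reversal) != 2L) return("undirected_dissimilar")
  sim <- cycle_branch_similarity(cycle, reversal, path_graph)
  if (sim >= similarity) "undirected_similar" else "undirected_dissimilar"
}

# Circular index sequence from position `from + 1` to `to` (inclusive).
circ_arc <- function(n, from, to) {
  idx <- (from + seq_len(n) - 1L) %% n + 1L
  idx[seq_len(which(idx == to)[1])]
}

# Identity between the two branch consensus sequences of an undirected cycle.
cycle_branch_similarity <- function(cycle, reversal, path_graph) {
  pg <- if (inherits(path_graph, "spanning_subgraph")) path_graph$pg else path_graph
  inner_tbl <- if (inherits(path_graph, "spanning_subgraph")) path_graph$inner else pg$inner
  n <- nrow(cycle)
  # the reversal junctions sit after edges reversal[1] and reversal[2]; the
  # two branches are the circular arcs between them
  arc1 <- circ_arc(n, reversal[1], reversal[2])
  arc2 <- circ_arc(n, reversal[2], reversal[1])
  seqs <- map_chr(list(arc1, arc2), function(arc) {
    rows <- cycle[arc, , drop = FALSE]
    rows <- rows[rows$type == "inner", , drop = FALSE]
    if (!nrow(rows)) return("")
    steps <- tibble(inner_id = rows$eid, enter_vertex = rows$from)
    lens <- setNames(pg$graph$vertices$length, pg$graph$vertices$id)
    tryCatch({
      pl <- walk_placements(inner_tbl, steps, lens)
      consensus_from_placements(pl, pg$graph, with_contained = FALSE)$seq
    }, error = function(e) "")
  })
  if (any(!nzchar(seqs))) return(0)
  # the two arcs traverse the cycle in the same circular direction, so the
  # second branch is seen reverse-complemented relative to the first
  max(global_identity(seqs[1], seqs[2]),
      global_identity(seqs[1], revcomp(seqs[2])))
}

# Global (end-to-end) identity of two sequences, in [0, 1].
global_identity <- function(s1, s2) {
  if (!nzchar(s1) || !nzchar(s2)) return(0)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(al) / max(nchar(s1), nchar(s2))
}

#' Build the spanning-treelike subgraph of a path graph
#'
#' Real edges are processed in descending score order (ties by id). An edge
#' introducing no cycle is selected; a directed cycle rejects the edge and
#' triggers [cut_directed_cycle()]; an undirected cycle is selected and
#' marked when its branches are similar, rejected otherwise. Bubbles already
#' present among parallel unique paths are classified the same way before any
#' real edge is placed. The result contains no directed cycle.
#'
#' @param path_graph A `path_graph`.
#' @param config An `asm_config`.
#' @param mean_read_len Mean read length (for the dangling-path threshold);
#'   estimated from the graph when `NULL`.
#' @return A `spanning_subgraph`.
#' @export
build_spanning_subgraph <- function(path_graph, config = assembly_config(),
                                    mean_read_len = NULL) {
  lens <- setNames(path_graph$graph$vertices$length, path_graph$graph$vertices$id)
  mean_rl <- mean_read_len %||% mean(lens)
  sg <- structure(list(
    pg = path_graph,
    inner = mutate(path_graph$inner, active = TRUE, dup_of = NA_character_),
    real_selected = tibble(real_id = character(0), v1 = character(0),
                           v2 = character(0), read = character(0),
                           score = numeric(0)),
    marked_cycles = list(),
    repeat_branches = tibble(cycle_id = integer(0), vertex = character(0),
                             read = character(0)),
    cut_cycles = list(),
    config = config,
    read_lens = lens,
    dangling_threshold = config$dangling_factor * mean_rl
  ), class = "spanning_subgraph")

  sg <- resolve_initial_bubbles(sg)

  scores <- score_real_edges(path_graph, config)
  real <- left_join(path_graph$real, scores, by = "real_id")
  real <- arrange(real, dplyr::desc(.data$combined), .data$real_id)
  for (i in seq_len(nrow(real))) {
    cand <- real[i, ]
    edges <- traversal_edges(sg)
    path <- find_path(edges, cand$v1, cand$v2)
    if (is.null(path)) {
      sg$real_selected <- bind_rows(sg$real_selected,
        tibble(real_id = cand$real_id, v1 = cand$v1, v2 = cand$v2,
               read = cand$read, score = cand$combined))
      next
    }
    cycle <- bind_rows(path,
                       tibble(eid = cand$real_id, type = "real",
                              v1 = cand$v1, v2 = cand$v2,
                              from = cand$v2, to = cand$v1))
    cls <- classify_cycle(cycle, sg, config$bubble_similarity)
    if (cls == "directed") {
      sg <- cut_directed_cycle(cycle, sg)
    } else if (cls == "undirected_similar") {
      sg <- collapse_marked_bubble(sg, cycle, cand)
    }
    # undirected_dissimilar: candidate simply not selected
  }
  sg
}

# Bubbles that exist before any real edge is selected: parallel unique paths
# between the same two vertices, and longer inner-only cycles.
resolve_initial_bubbles <- function(sg) {
  repeat {
    inner <- sg$inner[sg$inner$active, , drop = FALSE]
    if (nrow(inner) < 2L) return(sg)
    key <- paste(pmin(inner$v1, inner$v2), pmax(inner$v1, inner$v2))
    dup <- which(duplicated(key))
    if (length(dup)) {
      k <- key[dup[1]]
      pair <- inner[key == k, ][1:2, ]
      cycle <- tibble(eid = pair$inner_id, type = "inner",
                      v1 = pair$v1, v2 = pair$v2,
                      from = c(pair$v1[1], pair$v2[2]),
                      to = c(pair$v2[1], pair$v1[2]))
      cls <- classify_cycle(cycle, sg, sg$config$bubble_similarity)
      sg <- settle_inner_cycle(sg, cycle, cls)
      next
    }
    # general inner-only cycle (rare): use igraph
    g <- igraph::graph_from_data_frame(inner[, c("v1", "v2")], directed = FALSE)
    if (igraph::ecount(g) <= igraph::vcount(g) - igraph::count_components(g))
      return(sg)
    cyc <- igraph::girth(g)$circle
    vs <- igraph::as_ids(cyc)
    rows <- map_int(seq_along(vs), function(j) {
      a <- vs[j]; b <- vs[if (j == length(vs)) 1L else j + 1L]
      which((inner$v1 == a & inner$v2 == b) | (inner$v1 == b & inner$v2 == a))[1]
    })
    cycle <- tibble(eid = inner$inner_id[rows], type = "inner",
                    v1 = inner$v1[rows], v2 = inner$v2[rows],
                    from = vs, to = c(vs[-1], vs[1]))
    cls <- classify_cycle(cycle, sg, sg$config$bubble_similarity)
    sg <- settle_inner_cycle(sg, cycle, cls)
  }
}

# Resolve an inner-only cycle: similar bubbles are marked and collapsed onto
# the better-supported branch; dissimilar cycles are opened by re-homing one
# endpoint of the weakest branch so it survives as a separate spur.
settle_inner_cycle <- function(sg, cycle, cls) {
  ids <- cycle$eid[cycle$type == "inner"]
  rows <- sg$inner[sg$inner$inner_id %in% ids, ]
  weakest <- rows[order(rows$n_reads, rows$length, rows$inner_id), ][1, ]
  if (cls == "undirected_similar") {
    sg$marked_cycles[[length(sg$marked_cycles) + 1L]] <-
      list(type = "undirected_similar", edges = ids,
           collapsed = weakest$inner_id)
    sg$inner$active[sg$inner$inner_id == weakest$inner_id] <- FALSE
  } else {
    sg$marked_cycles[[length(sg$marked_cycles) + 1L]] <-
      list(type = "undirected_dissimilar", edges = ids, split = weakest$inner_id)
    i <- which(sg$inner$inner_id == weakest$inner_id)
    sg$inner$v1[i] <- paste0(sg$inner$v1[i], "*", i)
  }
  sg
}

# A similar undirected cycle (error/SNP bubble) is marked and collapsed onto
# its better-supported branch: the weaker arc between the two reversal
# vertices is dropped from traversal as a whole, so the kept branch remains
# traversable end to end. The candidate real edge is selected only when it
# lies on the kept arc.
collapse_marked_bubble <- function(sg, cycle, cand) {
  n <- nrow(cycle)
  nxt <- c(2:n, 1L)
  reversal <- which(cycle$type == "inner" & cycle$type[nxt] == "inner")
  arcs <- list(circ_arc(n, reversal[1], reversal[2]),
               circ_arc(n, reversal[2], reversal[1]))
  strength <- map_dbl(arcs, function(arc) {
    ids <- cycle$eid[arc][cycle$type[arc] == "inner"]
    sum(sg$inner$n_reads[sg$inner$inner_id %in% ids])
  })
  arc_len <- map_dbl(arcs, function(arc) {
    ids <- cycle$eid[arc][cycle$type[arc] == "inner"]
    sum(sg$inner$length[sg$inner$inner_id %in% ids])
  })
  weaker <- if (strength[1] != strength[2]) which.min(strength)
    else which.min(arc_len)
  drop_arc <- arcs[[weaker]]
  drop_inner <- cycle$eid[drop_arc][cycle$type[drop_arc] == "inner"]
  drop_real <- cycle$eid[drop_arc][cycle$type[drop_arc] == "real"]
  cand_dropped <- cand$real_id %in% drop_real
  sg$inner$active[sg$inner$inner_id %in% drop_inner] <- FALSE
  sg$real_selected <- sg$real_selected[
    !(sg$real_selected$real_id %in% drop_real), , drop = FALSE]
  if (!cand_dropped) {
    sg$real_selected <- bind_rows(sg$real_selected,
      tibble(real_id = cand$real_id, v1 = cand$v1, v2 = cand$v2,
             read = cand$read, score = cand$combined))
  }
  sg$marked_cycles[[length(sg$marked_cycles) + 1L]] <-
    list(type = "undirected_similar", edges = cycle$eid,
         collapsed = drop_inner)
  sg
}

#' Cut a directed cycle open at its branch vertices
#'
#' The cycle is first cleaned of short dangling paths (total sequence length
#' below the dangling threshold, strictly); the remaining cycle vertices with
#' attachments outside the cycle are branch vertices. The cycle's real edges
#' at branch vertices are removed and every cut vertex is recorded as a
#' repeat branch.
#'
#' @param cycle Ordered cycle edge tibble (the candidate real edge last).
#' @param subgraph A `spanning_subgraph`.
#' @return The updated `spanning_subgraph`.
#' @export
cut_directed_cycle <- function(cycle, subgraph) {
  sg <- subgraph
  cyc_vs <- unique(c(cycle$v1, cycle$v2))
  edges <- traversal_edges(sg)
  len_by_eid <- setNames(sg$inner$length, sg$inner$inner_id)
  non_cyc <- edges[!(edges$eid %in% cycle$eid), , drop = FALSE]
  # clip short hanging components off cycle vertices
  for (v in cyc_vs) {
    hang <- hanging_component(non_cyc, v, cyc_vs, len_by_eid)
    if (!is.null(hang) && hang$length < sg$dangling_threshold) {
      sg$inner$active[sg$inner$inner_id %in% hang$eids] <- FALSE
      sg$real_selected <- sg$real_selected[
        !(sg$real_selected$real_id %in% hang$eids), , drop = FALSE]
      non_cyc <- non_cyc[!(non_cyc$eid %in% hang$eids), , drop = FALSE]
    }
  }
  deg_out <- table(c(non_cyc$v1, non_cyc$v2))
  branch_vs <- cyc_vs[cyc_vs %in% names(deg_out)]
  cid <- length(sg$cut_cycles) + 1L
  cut_reals <- character(0)
  for (v in branch_vs) {
    at_v <- cycle[cycle$type == "real" & (cycle$v1 == v | cycle$v2 == v), ]
    cut_reals <- c(cut_reals, at_v$eid)
  }
  cut_reals <- unique(cut_reals)
  sg$real_selected <- sg$real_selected[
    !(sg$real_selected$real_id %in% cut_reals), , drop = FALSE]
  sg$repeat_branches <- bind_rows(sg$repeat_branches,
    tibble(cycle_id = cid, vertex = branch_vs,
           read = vertex_read(branch_vs)))
  sg$cut_cycles[[cid]] <- list(cycle = cycle, branch_vertices = branch_vs,
                               cut_reals = cut_reals)
  sg
}

# The connected component hanging off vertex v when the cycle vertices block
# traversal; NULL when v has no outside attachment or the attachment reaches
# another part of the graph through a cycle vertex.
hanging_component <- function(edges, v, blocked, len_by_eid) {
  if (!nrow(edges)) return(NULL)
  adj <- split(rep(seq_len(nrow(edges)), 2L), c(edges$v1, edges$v2))
  if (is.null(adj[[v]])) return(NULL)
  seen_v <- v
  seen_e <- integer(0)
  queue <- v
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (i in adj[[x]] %||% integer(0)) {
      if (i %in% seen_e) next
      seen_e <- c(seen_e, i)
      w <- if (edges$v1[i] == x) edges$v2[i] else edges$v1[i]
      if (w %in% blocked && w != v) return(NULL)  # reconnects to the cycle
      if (!(w %in% seen_v)) {
        seen_v <- c(seen_v, w)
        queue <- c(queue, w)
      }
    }
  }
  if (!length(seen_e)) return(NULL)
  sub <- edges[seen_e, , drop = FALSE]
  inner_ids <- sub$eid[sub$type == "inner"]
  list(eids = sub$eid, vertices = seen_v,
       length = sum(len_by_eid[inner_ids], na.rm = TRUE))
}

#' Detect and cut fragmentary directed cycles
#'
#' Repeats whose cycle did not close (an overlap was missed, e.g. due to
#' sequencing errors) leave a characteristic footprint: a path linking two
#' branch vertices, each of which is adjacent to at least one other short
#' path. Such branch vertices are recorded as repeat branches and their real
#' edges cut.
#'
#' @param subgraph A `spanning_subgraph`.
#' @return The updated `spanning_subgraph`.
#' @export
detect_fragmentary_cycles <- function(subgraph) {
  sg <- subgraph
  edges <- traversal_edges(sg)
  if (!nrow(edges)) return(sg)
  len_by_eid <- setNames(sg$inner$length, sg$inner$inner_id)
  adj <- split(rep(seq_len(nrow(edges)), 2L), c(edges$v1, edges$v2))
  deg <- lengths(adj)
  # short dangling path adjacent to a vertex: a hanging component below the
  # dangling threshold
  deg_get <- function(v) { d <- deg[v]; if (is.na(d)) 0L else unname(d) }
  has_short_path <- function(v, not_eid) {
    for (i in adj[[v]] %||% integer(0)) {
      e <- edges[i, ]
      if (e$eid == not_eid) next
      w <- if (e$v1 == v) e$v2 else e$v1
      if (e$type == "inner" && deg_get(w) == 1L &&
          len_by_eid[e$eid] < sg$dangling_threshold)
        return(TRUE)
    }
    FALSE
  }
  # a fragmentary cycle's linking path is a collapsed repeat: it carries the
  # reads of several copies, so its coverage is elevated relative to the
  # graph median
  med_cov <- stats::median(sg$inner$coverage[sg$inner$active])
  cov_by_eid <- setNames(sg$inner$coverage, sg$inner$inner_id)
  inner <- edges[edges$type == "inner", , drop = FALSE]
  for (i in seq_len(nrow(inner))) {
    e <- inner[i, ]
    u <- e$v1; v <- e$v2
    if (deg_get(u) >= 3L && deg_get(v) >= 3L &&
        cov_by_eid[e$eid] >= 1.5 * med_cov &&
        has_short_path(u, e$eid) && has_short_path(v, e$eid)) {
      cid <- length(sg$cut_cycles) + 1L
      ru <- vertex_read(u); rv <- vertex_read(v)
      cut <- sg$real_selected$read %in% c(ru, rv)
      cut_ids <- sg$real_selected$real_id[cut]
      sg$real_selected <- sg$real_selected[!cut, , drop = FALSE]
      sg$repeat_branches <- bind_rows(sg$repeat_branches,
        tibble(cycle_id = cid, vertex = c(u, v), read = c(ru, rv)))
      sg$cut_cycles[[cid]] <- list(
        cycle = tibble(eid = e$eid, type = "inner", v1 = u, v2 = v,
                       from = u, to = v),
        branch_vertices = c(u, v), cut_reals = cut_ids, fragmentary = TRUE)
      # refresh views
      edges <- traversal_edges(sg)
      adj <- split(rep(seq_len(nrow(edges)), 2L), c(edges$v1, edges$v2))
      deg <- lengths(adj)
      inner2 <- edges[edges$type == "inner", , drop = FALSE]
      if (!identical(inner2$eid, inner$eid)) inner <- inner2
    }
  }
  sg
}

#' Resolve cut repeats using mate-pair information
#'
#' For every cut cycle with exactly two repeat branches, mate pairs bridging
#' an entry path at one branch with an exit path at the other (implied span
#' within `insert_sd_tolerance` standard deviations of the insert size)
#' assign entries to exits. Each unambiguous assignment duplicates the
#' inter-branch repeat path and re-links one copy between its entry and exit;
#' unassigned branches stay cut.
#'
#' @param subgraph A `spanning_subgraph`.
#' @param reads Reads tibble carrying `mate_id`, `insert_size`, `insert_sd`.
#' @param min_support Minimal number of concordant bridging pairs per
#'   assignment.
#' @return The updated `spanning_subgraph`.
#' @export
resolve_repeats_with_mates <- function(subgraph, reads, min_support = 2L) {
  sg <- subgraph
  if (!length(sg$cut_cycles)) return(sg)
  mates <- reads[!is.na(reads$mate_id), c("id", "mate_id", "insert_size", "insert_sd")]
  if (!nrow(mates)) return(sg)
  lens <- sg$read_lens
  tol <- sg$config$insert_sd_tolerance

  for (cid in seq_along(sg$cut_cycles)) {
    cc <- sg$cut_cycles[[cid]]
    if (length(cc$branch_vertices) != 2L) next
    b1 <- cc$branch_vertices[1]; b2 <- cc$branch_vertices[2]
    r1 <- vertex_read(b1); r2 <- vertex_read(b2)
    if (r1 == r2) next
    # repeat path: for a fragmentary cycle, the recorded linking path; for a
    # cut directed cycle, the arc between the branch vertices that carried
    # the rejected/cut real edges (the last cycle row is the rejected
    # candidate)
    if (isTRUE(cc$fragmentary)) {
      rep_ids <- cc$cycle$eid[cc$cycle$type == "inner"]
    } else {
      cyc <- cc$cycle
      vseq <- c(cyc$from, cyc$to[nrow(cyc)])  # circular vertex sequence
      p1 <- which(vseq == b1)[1]; p2 <- which(vseq == b2)[1]
      lo <- min(p1, p2); hi <- max(p1, p2)
      arc_a <- seq(lo, hi - 1L)               # edges between the two vertices
      arc_b <- setdiff(seq_len(nrow(cyc)), arc_a)
      rep_arc <- if (nrow(cyc) %in% arc_a) arc_a else arc_b
      rep_ids <- cyc$eid[rep_arc][cyc$type[rep_arc] == "inner"]
    }
    rep_ids <- intersect(rep_ids, sg$inner$inner_id[sg$inner$active])
    # entries / exits: active inner edges at the branch reads that are not
    # part of the repeat path
    entry_ids <- setdiff(incident_inner_at_read(sg, r1), rep_ids)
    exit_ids <- setdiff(incident_inner_at_read(sg, r2), rep_ids)
    if (!length(rep_ids) || !length(entry_ids) || !length(exit_ids)) next

    rep_len <- sum(sg$inner$length[sg$inner$inner_id %in% rep_ids]) -
      sum(lens[c(r1, r2)])
    support <- matrix(0L, length(entry_ids), length(exit_ids),
                      dimnames = list(entry_ids, exit_ids))
    for (ei in entry_ids) {
      d1 <- read_dist_to_junction(sg, ei, r1)
      for (xi in exit_ids) {
        if (ei == xi) next
        d2 <- read_dist_to_junction(sg, xi, r2)
        m <- mates[mates$id %in% names(d1) & mates$mate_id %in% names(d2), ,
                   drop = FALSE]
        if (!nrow(m)) next
        span <- unname(d1[m$id]) + rep_len + unname(d2[m$mate_id])
        ok <- abs(span - m$insert_size) <=
          tol * pmax(m$insert_sd, 1L) + mean(lens)
        support[ei, xi] <- sum(ok)
      }
    }
    # greedy unambiguous assignment
    assigns <- list()
    while (TRUE) {
      mx <- max(support)
      if (mx < min_support) break
      hit <- which(support == mx, arr.ind = TRUE)
      if (nrow(hit) > 1L && anyDuplicated(hit[, 1]) || nrow(hit) > 1L && anyDuplicated(hit[, 2])) {
        warn("ambiguous mate support for repeat branch; leaving cut")
        break
      }
      e <- rownames(support)[hit[1, 1]]; x <- colnames(support)[hit[1, 2]]
      assigns[[length(assigns) + 1L]] <- c(entry = e, exit = x)
      support[hit[1, 1], ] <- -1L
      support[, hit[1, 2]] <- -1L
      if (all(support < 0)) break
    }
    if (!length(assigns)) next
    for (k in seq_along(assigns)) {
      sg <- duplicate_repeat_path(sg, cid, k, rep_ids,
                                  assigns[[k]][["entry"]], assigns[[k]][["exit"]],
                                  b1, b2)
    }
    # originals replaced by the linked copies
    sg$inner$active[sg$inner$inner_id %in% rep_ids] <- FALSE
  }
  sg
}

other_vertex_of_read <- function(v) {
  vertex_id(vertex_read(v), other_end(vertex_end(v)))
}

incident_inner <- function(sg, vs, exclude = character(0)) {
  inner <- sg$inner[sg$inner$active, ]
  inner$inner_id[(inner$v1 %in% vs | inner$v2 %in% vs) &
                   !(inner$inner_id %in% exclude)]
}

incident_inner_at_read <- function(sg, r) {
  vs <- c(vertex_id(r, "L"), vertex_id(r, "R"))
  incident_inner(sg, vs)
}

# distance (bases) from each read of an inner edge to the junction read's far
# end within that edge's layout
read_dist_to_junction <- function(sg, inner_id, junction_read) {
  row <- sg$inner[sg$inner$inner_id == inner_id, ]
  reads <- row$reads[[1]]; offs <- row$offsets[[1]]
  lens <- sg$read_lens
  jpos <- which(reads == junction_read)
  if (!length(jpos)) return(setNames(numeric(0), character(0)))
  jpos <- jpos[1]
  j_off <- offs[jpos]
  if (j_off > row$length / 2) {
    d <- (j_off + lens[[junction_read]]) - offs
  } else {
    d <- (offs + unname(lens[reads])) - j_off
  }
  setNames(pmax(d, 0), reads)
}

# Duplicate the repeat path and re-link one copy between an entry and an exit
# inner edge.
duplicate_repeat_path <- function(sg, cid, k, rep_ids, entry_id, exit_id,
                                  b1, b2) {
  sfx <- sprintf(".c%d.%d", cid, k)
  ren <- function(v) paste0(v, sfx)
  rep_rows <- sg$inner[sg$inner$inner_id %in% rep_ids, , drop = FALSE]
  dup <- rep_rows
  dup$inner_id <- paste0(dup$inner_id, sfx)
  dup$v1 <- ren(dup$v1); dup$v2 <- ren(dup$v2)
  dup$dup_of <- rep_rows$inner_id
  dup$active <- TRUE
  sg$inner <- bind_rows(sg$inner, dup)
  # interior selected real edges of the repeat path
  rep_vs <- unique(c(rep_rows$v1, rep_rows$v2))
  interior <- sg$real_selected[sg$real_selected$v1 %in% rep_vs &
                                 sg$real_selected$v2 %in% rep_vs, , drop = FALSE]
  if (nrow(interior)) {
    interior$real_id <- paste0(interior$real_id, sfx)
    interior$v1 <- ren(interior$v1); interior$v2 <- ren(interior$v2)
    sg$real_selected <- bind_rows(sg$real_selected, interior)
  }
  # re-home the entry and exit paths onto private junction vertices and link
  # them through the duplicated repeat
  rehome <- function(sg, path_id, read) {
    i <- which(sg$inner$inner_id == path_id)
    for (v in c("v1", "v2")) {
      if (vertex_read(sg$inner[[v]][i]) == read &&
          !grepl("\\.c[0-9]+\\.[0-9]+$", sg$inner[[v]][i])) {
        old <- sg$inner[[v]][i]
        sg$inner[[v]][i] <- ren(old)
        attr(sg, "last_rehomed") <- c(old, ren(old))
      }
    }
    sg
  }
  r1 <- vertex_read(b1); r2 <- vertex_read(b2)
  sg <- rehome(sg, entry_id, r1)
  sg <- rehome(sg, exit_id, r2)
  sg$real_selected <- bind_rows(sg$real_selected,
    tibble(real_id = paste0("R_", r1, sfx),
           v1 = ren(vertex_id(r1, "L")), v2 = ren(vertex_id(r1, "R")),
           read = r1, score = 0),
    tibble(real_id = paste0("R_", r2, sfx),
           v1 = ren(vertex_id(r2, "L")), v2 = ren(vertex_id(r2, "R")),
           read = r2, score = 0))
  sg
}

#' @export
print.spanning_subgraph <- function(x, ...) {
  cat(sprintf(paste0("<spanning_subgraph> %d active inner edges, %d selected real edges,\n",
                     "  %d marked cycles, %d repeat branches\n"),
              sum(x$inner$active), nrow(x$real_selected),
              length(x$marked_cycles), nrow(x$repeat_branches)))
  invisible(x)
}

# Directed-cycle freedom check (used by tests and assertions): for every
# selected real edge, the rest of the subgraph must not already provide an
# alternating (orientation-consistent) path between its endpoints.
has_directed_cycle <- function(subgraph) {
  edges <- traversal_edges(subgraph)
  for (i in which(edges$type == "real")) {
    e <- edges[i, ]
    p <- find_path(edges, e$v1, e$v2, skip_eid = e$eid)
    if (is.null(p)) next
    types <- p$type
    alternating <- all(types[-1] != types[-length(types)]) &&
      types[1] == "inner" && types[length(types)] == "inner"
    if (alternating) return(TRUE)
  }
  FALSE
}
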
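# Placement algebra -----------------------------------------------------------
#
# A placement is (offset, orient) of a read in some common layout frame:
# `offset` is the 0-based frame position of the read's first base (of its
# oriented sequence), `orient` whether the read's forward sequence ("F") or
# its reverse complement ("R") appears in the frame.
#
# An overlap/containment alignment (a, b, orient o, diag d) states that the
# oriented b starts at position d of a's forward frame.  Given a's placement,
# b's placement follows (and vice versa).
place_b_from_a <- function(off_a, or_a, la, lb, d, o) {
  or_b <- compose_orient(or_a, o)
  off_b <- ifelse(or_a == "F", off_a + d, off_a + la - d - lb)
  list(offset = off_b, orient = or_b)
}

place_a_from_b <- function(off_b, or_b, la, lb, d, o) {
  or_a <- compose_orient(or_b, o)
  off_a <- ifelse(or_a == "F", off_b - d, off_b - (la - d - lb))
  list(offset = off_a, orient = or_a)
}

#' Build an overlap graph from reads and alignments
#'
#' One vertex per read, one edge per alignment (overlap or containment).
#' Edge weight is the alignment length; edge score the alignment score.
#' Duplicate alignments for the same pair and orientation keep the higher
#' score.
#'
#' @param reads Reads tibble.
#' @param alignments Alignment tibble (from [compute_overlaps()] or
#'   [align_overlap()]).
#' @return An `overlap_graph`: list with `vertices` (id, length), `edges`
#'   (alignments plus `edge_id`), `exemplar_of` (filled by
#'   [reduce_containments()]), and `reads`.
#' @export
build_overlap_graph <- function(reads, alignments) {
  unknown <- setdiff(unique(c(alignments$read_a, alignments$read_b)), reads$id)
  if (length(unknown))
    abort(paste0("alignment cites unknown read(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  edges <- dedup_alignments(alignments)
  edges$edge_id <- seq_len(nrow(edges))
  structure(list(
    vertices = tibble(id = reads$id, length = nchar(reads$seq)),
    edges = edges,
    exemplar_of = tibble(read = character(0), exemplar = character(0),
                         offset = integer(0), orient = character(0)),
    reads = reads
  ), class = "overlap_graph")
}

#' Choose exemplars and remove overlap edges of contained reads
#'
#' Within each connected component of the containment edges, the exemplar is
#' the longest read; ties break by the highest summed alignment score to the
#' other reads of the component, then by lexicographic id. All overlap edges
#' incident to the non-exemplar (contained) reads are removed; the reads
#' themselves are retained, with their placement relative to the exemplar
#' recorded in `exemplar_of`, so that consensus calling can still use them.
#'
#' @param graph An `overlap_graph`.
#' @return The reduced `overlap_graph`.
#' @export
reduce_containments <- function(graph) {
  ct <- graph$edges[graph$edges$kind == "containment", , drop = FALSE]
  if (!nrow(ct)) return(graph)
  g <- igraph::graph_from_data_frame(
    ct[, c("read_a", "read_b")], directed = FALSE,
    vertices = graph$vertices$id)
  comp <- igraph::components(g)$membership
  lens <- setNames(graph$vertices$length, graph$vertices$id)
  in_ct <- names(comp)[names(comp) %in% unique(c(ct$read_a, ct$read_b))]
  comp <- comp[in_ct]

  score_sum <- c(tapply(ct$score, ct$read_a, sum), tapply(ct$score, ct$read_b, sum))
  score_by_read <- tapply(score_sum, names(score_sum), sum)

  exemplars <- tapply(names(comp), comp, function(ids) {
    l <- lens[ids]
    ids <- ids[l == max(l)]
    if (length(ids) > 1L) {
      s <- score_by_read[ids]; s[is.na(s)] <- 0
      ids <- ids[s == max(s)]
    }
    sort(ids)[1]
  })
  exemplar_of_read <- setNames(exemplars[as.character(comp)], names(comp))
  contained_reads <- names(exemplar_of_read)[exemplar_of_read != names(exemplar_of_read)]

  # placements of contained reads in their exemplar's frame, composed along
  # containment edges by BFS from each exemplar
  placements <- list()
  for (cmp in unique(comp)) {
    ids <- names(comp)[comp == cmp]
    ex <- exemplars[[as.character(cmp)]]
    sub <- ct[ct$read_a %in% ids & ct$read_b %in% ids, , drop = FALSE]
    place <- list()
    place[[ex]] <- c(offset = 0L, orient = "F")
    queue <- ex
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- place[[cur]]
      touch <- sub[sub$read_a == cur | sub$read_b == cur, , drop = FALSE]
      for (i in seq_len(nrow(touch))) {
        e <- touch[i, ]
        nb <- if (e$read_a == cur) e$read_b else e$read_a
        if (!is.null(place[[nb]])) next
        la <- lens[[e$read_a]]; lb <- lens[[e$read_b]]
        if (e$read_a == cur) {
          np <- place_b_from_a(as.integer(p[["offset"]]), p[["orient"]],
                               la, lb, e$diag, e$orient)
        } else {
          np <- place_a_from_b(as.integer(p[["offset"]]), p[["orient"]],
                               la, lb, e$diag, e$orient)
        }
        place[[nb]] <- c(offset = np$offset, orient = np$orient)
        queue <- c(queue, nb)
      }
    }
    for (id in setdiff(ids, ex)) {
      pl <- place[[id]]
      if (is.null(pl)) next
      placements[[length(placements) + 1L]] <-
        tibble(read = id, exemplar = ex,
               offset = as.integer(pl[["offset"]]), orient = pl[["orient"]])
    }
  }
  graph$exemplar_of <- bind_rows(placements) %||%
    tibble(read = character(0), exemplar = character(0),
           offset = integer(0), orient = character(0))

  keep <- !(graph$edges$kind == "overlap" &
              (graph$edges$read_a %in% contained_reads |
                 graph$edges$read_b %in% contained_reads))
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph
}

# Reads that remain assembly vertices after containment reduction.
active_reads <- function(graph) {
  setdiff(graph$vertices$id, graph$exemplar_of$read)
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("<overlap_graph> %d reads, %d overlap edges, %d containment edges, %d contained\n",
              nrow(x$vertices), sum(x$edges$kind == "overlap"),
              sum(x$edges$kind == "containment"), nrow(x$exemplar_of)))
  invisible(x)
}

#' Remove transitive overlap edges
#'
#' An overlap edge `(v1, v2)` with weight `w_t` is transitive when two edges
#' `(v1, w)` and `(w, v2)` exist, consistent in orientation and read ends,
#' with weights `w_1 >= w_t` and `w_2 >= w_t`. All transitive edges are marked
#' against the original edge set and removed together, so the result does not
#' depend on edge processing order; equal-weight triangles remove the
#' (weakly) lightest edge. Containment edges are not touched.
#'
#' @param graph A containment-reduced `overlap_graph`.
#' @return The reduced `overlap_graph`.
#' @export
transitive_reduction <- function(graph) {
  ov <- graph$edges[graph$edges$kind == "overlap", , drop = FALSE]
  if (nrow(ov) < 3L) return(graph)
  # directed half-edge view: one row per traversal direction
  fwd <- tibble(from = ov$read_a, from_end = ov$end_a,
                to = ov$read_b, to_end = ov$end_b,
                orient = ov$orient, weight = ov$length, edge_id = ov$edge_id)
  rev <- tibble(from = ov$read_b, from_end = ov$end_b,
                to = ov$read_a, to_end = ov$end_a,
                orient = ov$orient, weight = ov$length, edge_id = ov$edge_id)
  dir <- bind_rows(fwd, rev)

  # e1: v -> w arriving at w's end X; e2 must leave w from the other end
  two <- inner_join(dir, dir, by = c("to" = "from"),
                    suffix = c("_1", "_2"), relationship = "many-to-many")
  names(two)[names(two) == "to"] <- "w"
  two <- two[two$to_end_1 != two$from_end_2 & two$edge_id_1 != two$edge_id_2, ,
             drop = FALSE]
  if (!nrow(two)) return(graph)
  cand <- tibble(from = two$from, from_end = two$from_end_1,
                 to = two$to_2, to_end = two$to_end_2,
                 orient = compose_orient(two$orient_1, two$orient_2),
                 wmin = pmin(two$weight_1, two$weight_2),
                 e1 = two$edge_id_1, e2 = two$edge_id_2)
  hit <- inner_join(dir, cand,
                    by = c("from", "from_end", "to", "to_end", "orient"),
                    relationship = "many-to-many")
  hit <- hit[hit$weight <= hit$wmin & hit$edge_id != hit$e1 &
               hit$edge_id != hit$e2, , drop = FALSE]
  drop_ids <- unique(hit$edge_id)
  graph$edges <- graph$edges[!(graph$edges$edge_id %in% drop_ids), , drop = FALSE]
  graph
}
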
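#' Partition mapped reads into reference blocks
#'
#' The reference is tiled into consecutive windows of `block_len` bases
#' (0-based half-open; the trailing partial window is a block). A read
#' belongs to the block containing its `ref_start`.
#'
#' @param mapped_reads Tibble with at least `read_id`-like `id` (or
#'   `read_id`) and `ref_start` columns.
#' @param reference Reference DNA string (or its length).
#' @param block_len Block length in bases.
#' @return A blocks tibble: `block` (0-based index), `start`, `end`
#'   (half-open) and `read_ids` (list column).
#' @export
partition_blocks <- function(mapped_reads, reference, block_len) {
  L <- if (is.character(reference)) nchar(reference) else as.integer(reference)
  block_len <- as.integer(block_len)
  if (block_len < 1L) abort("`block_len` must be positive")
  n_blocks <- max(1L, as.integer(ceiling(L / block_len)))
  ids <- mapped_reads[["read_id"]] %||% mapped_reads[["id"]]
  rs <- mapped_reads$ref_start
  if (any(rs < 0L | rs >= L))
    abort("mapped read ref_start outside the reference")
  b <- as.integer(rs %/% block_len)
  tibble(
    block = seq_len(n_blocks) - 1L,
    start = (seq_len(n_blocks) - 1L) * block_len,
    end = pmin(seq_len(n_blocks) * block_len, L),
    read_ids = map(seq_len(n_blocks) - 1L, function(k) ids[b == k])
  )
}

#' Build the reusable left-over overlap graph
#'
#' Left-over reads (reads absent from the alignment set) are quality-filtered
#' (mean Phred at least `min_leftover_phred`, at most `max_leftover_n` N
#' bases), then indexed and overlapped once. The result is immutable and is
#' reused by every block assembly; recruitment only reads from it.
#'
#' @param leftover_reads Reads tibble.
#' @param config An [assembly_config()].
#' @return A `leftover_graph`: list with the filtered `reads`, their kmer
#'   `index`, and the `edges` alignment tibble.
#' @export
build_leftover_graph <- function(leftover_reads, config = assembly_config()) {
  reads <- leftover_reads
  if (nrow(reads)) {
    n_count <- stringi::stri_count_fixed(reads$seq, "N")
    mean_q <- map_dbl(reads$qual, function(q) if (is.null(q)) Inf else mean(q))
    reads <- reads[n_count <= config$max_leftover_n &
                     mean_q >= config$min_leftover_phred, , drop = FALSE]
  }
  edges <- compute_overlaps(reads, config, tag = "leftover")
  idx <- if (nrow(reads)) index_kmers(reads, config$kmer_size,
                                      config$single_strand) else NULL
  structure(list(reads = reads, index = idx, edges = edges, config = config),
            class = "leftover_graph")
}

#' @export
print.leftover_graph <- function(x, ...) {
  cat(sprintf("<leftover_graph> %d reads, %d edges\n",
              nrow(x$reads), nrow(x$edges)))
  invisible(x)
}

#' Recruit left-over reads into a local overlap graph
#'
#' Bridging overlap alignments between the local reads and the left-over pool
#' are computed against the left-over graph's persistent kmer index. Left-over
#' reads with at least one qualifying bridge seed the recruitment; the seed
#' set is closed within the left-over graph up to `recruit_radius` hops
#' (the full connected component by default, capped at
#' `max_recruit_reads`). The merged graph is the union of the local graph,
#' the induced left-over subgraph and the bridge edges; the left-over graph
#' itself is never modified.
#'
#' @param local_graph An `overlap_graph` over the block's reads.
#' @param leftover A `leftover_graph`.
#' @param config An [assembly_config()].
#' @return The merged `overlap_graph` (with a `recruited` attribute listing
#'   the recruited left-over read ids).
#' @export
recruit_and_merge <- function(local_graph, leftover,
                              config = assembly_config()) {
  if (is.null(leftover) || !nrow(leftover$reads)) {
    attr(local_graph, "recruited") <- character(0)
    return(local_graph)
  }
  local_reads <- local_graph$reads
  bump_counter("bridge")
  idx_local <- index_kmers(local_reads, config$kmer_size, config$single_strand)
  cands <- candidate_pairs(idx_local, leftover$index,
                           max_occ = config$max_kmer_occ)
  seqs <- c(setNames(local_reads$seq, local_reads$id),
            setNames(leftover$reads$seq, leftover$reads$id))
  bridges <- dedup_alignments(align_candidates(cands, seqs, config))
  lo_ids <- leftover$reads$id
  seed <- unique(c(bridges$read_a[bridges$read_a %in% lo_ids],
                   bridges$read_b[bridges$read_b %in% lo_ids]))
  if (!length(seed)) {
    attr(local_graph, "recruited") <- character(0)
    return(local_graph)
  }
  # close the seed set within the left-over graph
  recruited <- seed
  if (nrow(leftover$edges) && config$recruit_radius > 0) {
    g <- igraph::graph_from_data_frame(
      leftover$edges[, c("read_a", "read_b")], directed = FALSE,
      vertices = lo_ids)
    if (is.infinite(config$recruit_radius)) {
      comp <- igraph::components(g)$membership
      recruited <- names(comp)[comp %in% unique(comp[seed])]
    } else {
      nb <- igraph::ego(g, order = config$recruit_radius,
                        nodes = seed, mode = "all")
      recruited <- unique(c(seed, unlist(lapply(nb, igraph::as_ids))))
    }
  }
  if (length(recruited) > config$max_recruit_reads)
    recruited <- head(sort(recruited), config$max_recruit_reads)
  lo_sub <- leftover$reads[leftover$reads$id %in% recruited, , drop = FALSE]
  lo_edges <- leftover$edges[leftover$edges$read_a %in% recruited &
                               leftover$edges$read_b %in% recruited, ,
                             drop = FALSE]
  bridges <- bridges[
    (bridges$read_a %in% c(local_reads$id, recruited)) &
      (bridges$read_b %in% c(local_reads$id, recruited)), , drop = FALSE]
  merged_reads <- bind_rows(local_reads, lo_sub)
  cols <- intersect(names(local_graph$edges), names(lo_edges))
  merged_edges <- bind_rows(local_graph$edges[, cols],
                            lo_edges[, cols], bridges[, cols])
  merged <- build_overlap_graph(merged_reads, merged_edges)
  attr(merged, "recruited") <- recruited
  merged
}

#' Apply distance-dependent alignment constraints
#'
#' Overlap edges between two mapped reads must satisfy the `(min_len,
#' max_mm)` tier selected by the reference distance between the reads;
#' edges with an unmapped endpoint use the global defaults. Tiers are given
#' as a tibble `(max_dist, min_len, max_mm)` evaluated in order of
#' increasing `max_dist` (the first tier with `dist <= max_dist` applies; a
#' final `Inf` row catches the rest), or as a function `dist ->
#' list(min_len, max_mm)`.
#'
#' @param local_graph An `overlap_graph`.
#' @param mapped_reads Tibble with `read_id`/`id` and `ref_start`.
#' @param constraint Tiers tibble or function; `NULL` leaves the graph
#'   unchanged.
#' @return The filtered `overlap_graph`.
#' @export
distance_constrained_overlaps <- function(local_graph, mapped_reads,
                                          constraint = NULL) {
  if (is.null(constraint)) return(local_graph)
  ids <- mapped_reads[["read_id"]] %||% mapped_reads[["id"]]
  pos <- setNames(mapped_reads$ref_start, ids)
  e <- local_graph$edges
  pa <- pos[e$read_a]; pb <- pos[e$read_b]
  both <- !is.na(pa) & !is.na(pb)
  dist <- abs(pa - pb)
  tier_of <- function(d) {
    if (is.function(constraint)) {
      t <- constraint(d)
      c(min_len = t$min_len, max_mm = t$max_mm)
    } else {
      tiers <- constraint[order(constraint$max_dist), ]
      i <- which(d <= tiers$max_dist)[1]
      if (is.na(i)) i <- nrow(tiers)
      c(min_len = tiers$min_len[i], max_mm = tiers$max_mm[i])
    }
  }
  keep <- rep(TRUE, nrow(e))
  for (i in which(both & e$kind == "overlap")) {
    t <- tier_of(dist[i])
    keep[i] <- e$length[i] >= t[["min_len"]] && e$mismatches[i] <= t[["max_mm"]]
  }
  local_graph$edges <- e[keep, , drop = FALSE]
  local_graph
}

#' Assemble one reference block, optionally recruiting left-over reads
#'
#' Runs the full pipeline on the block's mapped reads: overlap computation,
#' optional distance constraints, left-over recruitment from the persistent
#' left-over graph, containment/transitive reduction, path graph, layout and
#' consensus. Contigs are labelled with the block id.
#'
#' @param block One row of [partition_blocks()] output.
#' @param reads Full reads tibble (mapped reads are looked up by id).
#' @param leftover A `leftover_graph`, or `NULL` to disable recruitment.
#' @param config An [assembly_config()].
#' @param mapped_reads Optional mapped-read tibble (for distance
#'   constraints).
#' @param constraint Optional distance-constraint tiers (see
#'   [distance_constrained_overlaps()]).
#' @return An `assembly`; its contigs carry a `block` column.
#' @export
assemble_block <- function(block, reads, leftover = NULL,
                           config = assembly_config(),
                           mapped_reads = NULL, constraint = NULL) {
  ids <- block$read_ids[[1]]
  block_reads <- reads[reads$id %in% ids, , drop = FALSE]
  if (!nrow(block_reads)) {
    out <- structure(list(contigs = empty_contigs(), graph = NULL,
                          path_graph = NULL, subgraph = NULL, config = config),
                     class = "assembly")
    out$contigs$block <- integer(0)
    return(out)
  }
  aln <- compute_overlaps(block_reads, config, tag = "local")
  graph <- build_overlap_graph(block_reads, aln)
  if (!is.null(constraint) && !is.null(mapped_reads))
    graph <- distance_constrained_overlaps(graph, mapped_reads, constraint)
  if (!is.null(leftover))
    graph <- recruit_and_merge(graph, leftover, config)
  asm <- assemble_from_graph(graph, config,
                             prefix = sprintf("b%d_ctg", block$block))
  if (nrow(asm$contigs)) asm$contigs$block <- block$block
  else asm$contigs$block <- integer(0)
  asm$recruited <- attr(asm$graph, "recruited") %||%
    attr(graph, "recruited") %||% character(0)
  asm
}

#' Homology-guided assembly of all blocks
#'
#' The SUPERLOCAS-style workflow: build the left-over graph once, partition
#' the mapped reads into blocks, and assemble every block against the shared
#' left-over graph.
#'
#' @param reads Full reads tibble.
#' @param alignments Mapped-read tibble (`read_id`, `ref_start`, ...).
#' @param reference Reference DNA string.
#' @param config An [assembly_config()].
#' @param leftover Pre-built `leftover_graph`; built from the unaligned reads
#'   when `NULL`.
#' @param recruit Recruit left-over reads (`TRUE`) or run plain per-block
#'   assembly (`FALSE`).
#' @param reuse_leftover Reuse one left-over graph across blocks (default);
#'   `FALSE` re-pools and re-overlaps the left-over reads for every block
#'   (the naive baseline, for comparison only).
#' @param constraint Optional distance-constraint tiers.
#' @return A list with `contigs` (bound tibble across blocks, with `block`
#'   column), `blocks`, `assemblies` (per block), and `leftover`.
#' @export
assemble_blocks <- function(reads, alignments, reference,
                            config = assembly_config(), leftover = NULL,
                            recruit = TRUE, reuse_leftover = TRUE,
                            constraint = NULL) {
  blocks <- partition_blocks(alignments, reference, config$block_len)
  lo_reads <- reads[!(reads$id %in% alignments$read_id), , drop = FALSE]
  if (recruit && is.null(leftover) && reuse_leftover)
    leftover <- build_leftover_graph(lo_reads, config)
  assemblies <- map(seq_len(nrow(blocks)), function(i) {
    lo <- if (!recruit) NULL
      else if (reuse_leftover) leftover
      else build_leftover_graph(lo_reads, config)
    assemble_block(blocks[i, ], reads, lo, config,
                   mapped_reads = alignments, constraint = constraint)
  })
  contigs <- bind_rows(map(assemblies, function(a) a$contigs))
  list(contigs = contigs, blocks = blocks, assemblies = assemblies,
       leftover = leftover)
}
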
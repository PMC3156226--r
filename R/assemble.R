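#' Assemble a read set de novo
#'
#' Runs the full overlap-layout-consensus pipeline: kmer-seeded overlap
#' detection, overlap-graph construction, containment (exemplar) and
#' transitive reduction, path-graph condensation, greedy spanning-subgraph
#' layout with cycle resolution (mate pairs, when present, re-link cut repeat
#' branches), and majority-vote consensus.
#'
#' @param reads Reads tibble (see [load_reads()] / [simulate_reads()]).
#' @param config An [assembly_config()].
#' @param use_mates Resolve cut repeats with mate pairs when the reads carry
#'   mate links (default `TRUE`).
#' @param tag Overlap-pass counter tag for this pool.
#' @return An `assembly` object: list with `contigs` (tibble: `id`, `seq`,
#'   `length`, `read_path`, `support`, `n_reads`), plus the intermediate
#'   `graph`, `path_graph` and `subgraph`.
#' @examples
#' g <- random_reference(1500, seed = 1)
#' rd <- simulate_reads(g, depth = 12, read_len = 80, seed = 2)
#' asm <- assemble(rd)
#' asm$contigs$length
#' @export
assemble <- function(reads, config = assembly_config(), use_mates = TRUE,
                     tag = "local") {
  if (!nrow(reads)) {
    return(structure(list(contigs = empty_contigs(), graph = NULL,
                          path_graph = NULL, subgraph = NULL,
                          config = config), class = "assembly"))
  }
  aln <- compute_overlaps(reads, config, tag = tag)
  assemble_from_graph(build_overlap_graph(reads, aln), config, use_mates)
}

empty_contigs <- function() {
  tibble(id = character(0), seq = character(0), length = integer(0),
         read_path = list(), support = list(), n_reads = integer(0))
}

# Shared back half of the pipeline, entered with a built overlap graph
# (the homology-guided mode arrives here with a merged graph).
assemble_from_graph <- function(graph, config, use_mates = TRUE,
                                prefix = "ctg") {
  graph <- reduce_containments(graph)
  graph <- transitive_reduction(graph)
  pg <- build_path_graph(graph)
  if (!nrow(pg$inner)) {
    return(structure(list(contigs = empty_contigs(), graph = graph,
                          path_graph = pg, subgraph = NULL, config = config),
                     class = "assembly"))
  }
  sg <- build_spanning_subgraph(pg, config)
  sg <- detect_fragmentary_cycles(sg)
  if (use_mates && any(!is.na(graph$reads$mate_id)))
    sg <- resolve_repeats_with_mates(sg, graph$reads)
  contigs <- contigs_from_subgraph(sg, prefix = prefix)
  structure(list(contigs = contigs, graph = graph, path_graph = pg,
                 subgraph = sg, config = config), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d contigs, total %d bp (longest %s bp)\n",
              nrow(x$contigs), sum(x$contigs$length),
              if (nrow(x$contigs)) max(x$contigs$length) else "-"))
  invisible(x)
}
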
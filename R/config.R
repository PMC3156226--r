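#' Assembly configuration
#'
#' Collects the tunable parameters of the assembler in one list. Defaults are
#' chosen for 80 bp reads at 5-15x depth, the operating regime the assembler
#' targets.
#'
#' @param kmer_size Exact-kmer seed length for overlap candidate detection.
#'   Candidate read pairs are pairs sharing at least one identical kmer
#'   (canonical over both strands). Must satisfy `4 <= kmer_size <=` shortest
#'   read length.
#' @param min_overlap Minimal length (bases) of a suffix-prefix overlap
#'   alignment. Containments (full-length alignments) are exempt.
#' @param max_mismatches Maximal number of mismatches allowed in an overlap or
#'   containment alignment. Alignments are gap-free.
#' @param match_score,mismatch_penalty Scoring of alignment columns; the edge
#'   score of an alignment is `matches * match_score + mismatches *
#'   mismatch_penalty`.
#' @param lambda_score Weight of the alignment-quality term in the real-edge
#'   score `lambda * quality + (1 - lambda) * min(coverage / coverage_target,
#'   1)`; the remainder weights normalised read coverage.
#' @param coverage_target Coverage at which the coverage term of the real-edge
#'   score saturates. `NULL` (default) estimates it as twice the median
#'   per-path read coverage of the path graph.
#' @param dangling_factor Dangling paths (graph tips) shorter than
#'   `dangling_factor * mean(read length)` bases are clipped when a directed
#'   cycle is cleaned, and define the "short path" rule for fragmentary
#'   cycles.
#' @param bubble_similarity Global-identity threshold at or above which the two
#'   branches of an undirected cycle are considered similar (sequencing
#'   error/SNP bubble) rather than a false alignment.
#' @param insert_sd_tolerance Number of insert-size standard deviations within
#'   which a mate pair is accepted as bridging two repeat branches.
#' @param max_kmer_occ Kmers occurring more often than this in the index are
#'   skipped when seeding candidates (simple high-copy-repeat guard).
#' @param min_leftover_phred,max_leftover_n Quality filter for left-over reads:
#'   mean Phred quality must be at least `min_leftover_phred` (reads without
#'   qualities pass) and at most `max_leftover_n` N bases are allowed.
#' @param max_recruit_reads Safety cap on the number of left-over reads
#'   recruited into one block assembly.
#' @param recruit_radius Expansion radius (in graph hops) for left-over
#'   recruitment around bridged seed reads; `Inf` (default) recruits the full
#'   connected component.
#' @param block_len Reference block length (bases) for homology-guided
#'   assembly.
#' @param single_strand If `TRUE`, reads are assumed pre-oriented and
#'   reverse-complement overlaps are not searched.
#' @param longest_path_fixpoint If `TRUE`, the longest-path re-calculation
#'   during path extraction is iterated to a fixpoint instead of the default
#'   single re-iteration.
#'
#' @return A list of class `asm_config`.
#' @examples
#' cfg <- assembly_config(min_overlap = 30)
#' cfg$min_overlap
#' @export
assembly_config <- function(kmer_size = 13L,
                            min_overlap = 25L,
                            max_mismatches = 2L,
                            match_score = 1,
                            mismatch_penalty = -2,
                            lambda_score = 0.5,
                            coverage_target = NULL,
                            dangling_factor = 2,
                            bubble_similarity = 0.90,
                            insert_sd_tolerance = 3,
                            max_kmer_occ = 100L,
                            min_leftover_phred = 20,
                            max_leftover_n = 1L,
                            max_recruit_reads = 20000L,
                            recruit_radius = Inf,
                            block_len = 25000L,
                            single_strand = FALSE,
                            longest_path_fixpoint = FALSE) {
  if (kmer_size < 4L) abort("`kmer_size` must be at least 4")
  if (min_overlap < kmer_size)
    abort("`min_overlap` must be at least `kmer_size`")
  if (max_mismatches < 0L) abort("`max_mismatches` must be non-negative")
  structure(list(
    kmer_size = as.integer(kmer_size),
    min_overlap = as.integer(min_overlap),
    max_mismatches = as.integer(max_mismatches),
    match_score = match_score,
    mismatch_penalty = mismatch_penalty,
    lambda_score = lambda_score,
    coverage_target = coverage_target,
    dangling_factor = dangling_factor,
    bubble_similarity = bubble_similarity,
    insert_sd_tolerance = insert_sd_tolerance,
    max_kmer_occ = as.integer(max_kmer_occ),
    min_leftover_phred = min_leftover_phred,
    max_leftover_n = as.integer(max_leftover_n),
    max_recruit_reads = as.integer(max_recruit_reads),
    recruit_radius = recruit_radius,
    block_len = as.integer(block_len),
    single_strand = isTRUE(single_strand),
    longest_path_fixpoint = isTRUE(longest_path_fixpoint)
  ), class = "asm_config")
}

#' @export
print.asm_config <- function(x, ...) {
  cat("<asm_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]] %||% "auto")))
  invisible(x)
}
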
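# Contig placement -------------------------------------------------------
#
# Contigs produced from substitution-error reads are gap-free with respect to
# the sequence they assemble, so placement anchors exact kmers of the contig
# in the block sequence and evaluates full-contig mismatch counts on the
# implied diagonals (both orientations). When no anchor matches (highly
# diverged or spurious contigs) and the problem is small, a free-end-gap
# alignment is used as fallback.

place_contig <- function(contig_seq, block_seq, anchor_k = 24L,
                         max_anchors = 48L) {
  lc <- nchar(contig_seq); lb <- nchar(block_seq)
  best <- list(mm_frac = 1, start = NA_integer_, strand = NA_character_,
               mismatches = NA_integer_)
  k <- min(anchor_k, lc)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig_seq else revcomp(contig_seq)
    offs <- unique(round(seq(0L, lc - k, length.out = min(max_anchors,
                                                          max(1L, lc - k + 1L)))))
    diags <- integer(0)
    subj <- Biostrings::DNAString(block_seq)
    for (o in offs) {
      anchor <- substring(s, o + 1L, o + k)
      if (grepl("N", anchor, fixed = TRUE)) next
      m <- Biostrings::matchPattern(anchor, subj)
      if (length(m)) diags <- c(diags, Biostrings::start(m) - 1L - o)
    }
    for (d in unique(diags)) {
      # contig occupies block positions [d, d + lc); out-of-block columns
      # count as mismatches
      lo <- max(0L, d); hi <- min(lb, d + lc)
      if (hi <= lo) next
      mm_in <- count_mismatches(substring(block_seq, lo + 1L, hi),
                                substring(s, lo - d + 1L, hi - d))
      mm <- mm_in + (lc - (hi - lo))
      if (mm / lc < best$mm_frac) {
        best <- list(mm_frac = mm / lc, start = d, strand = strand,
                     mismatches = as.integer(mm))
      }
    }
  }
  if (is.na(best$start) && as.double(lc) * lb <= 4e7) {
    # alignment fallback for contigs without exact anchors
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contig_seq else revcomp(contig_seq)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(block_seq),
        type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 4, gapExtension = 1)
      errs <- lc - Biostrings::nmatch(al)
      if (errs / lc < best$mm_frac) {
        best <- list(mm_frac = errs / lc,
                     start = Biostrings::start(
                       Biostrings::subject(al)) - 1L,
                     strand = strand, mismatches = as.integer(errs))
      }
    }
  }
  best
}

#' Partition contigs into valid and invalid
#'
#' A contig is valid when its best global (free-end-gap) alignment to the
#' block's target sequence has a mismatch fraction of at most `max_mm_frac`
#' (both orientations are tried; mismatch fraction is over contig columns).
#'
#' @param contigs Contigs tibble.
#' @param target_block_seq The block's true sequence.
#' @param max_mm_frac Validity threshold (default 0.10).
#' @return The contigs tibble with placement columns (`mm_frac`,
#'   `mismatches`, `place_start`, `place_strand`) and logical `valid`.
#' @export
valid_contigs <- function(contigs, target_block_seq, max_mm_frac = 0.10) {
  if (!nrow(contigs)) {
    contigs$mm_frac <- numeric(0); contigs$mismatches <- integer(0)
    contigs$place_start <- integer(0); contigs$place_strand <- character(0)
    contigs$valid <- logical(0)
    return(contigs)
  }
  pl <- map(contigs$seq, place_contig, block_seq = target_block_seq)
  contigs$mm_frac <- map_dbl(pl, "mm_frac")
  contigs$mismatches <- map_int(pl, function(p) p$mismatches)
  contigs$mismatches <- ifelse(is.na(contigs$mismatches),
                               nchar(contigs$seq), contigs$mismatches)
  contigs$place_start <- map_int(pl, function(p) p$start %||% NA_integer_)
  contigs$place_strand <- map_chr(pl, function(p) p$strand %||% NA_character_)
  contigs$valid <- contigs$mm_frac <= max_mm_frac
  contigs
}

#' Block N50 (positional definition)
#'
#' The length of the longest contig such that all valid contigs of equal or
#' longer length cover at least 50\% of the positions of the block sequence;
#' 0 when no length threshold achieves that. Each position counts once even
#' under overlapping contigs.
#'
#' @param contigs Output of [valid_contigs()] (invalid rows are ignored).
#' @param block_seq The block sequence (for its length).
#' @param frac Required covered fraction (0.5).
#' @return N50 in bases.
#' @export
block_n50 <- function(contigs, block_seq, frac = 0.5) {
  lb <- nchar(block_seq)
  v <- contigs[contigs$valid & !is.na(contigs$place_start), , drop = FALSE]
  if (!nrow(v)) return(0L)
  v <- v[order(-v$length), , drop = FALSE]
  covered <- logical(lb)
  lengths_desc <- unique(v$length)
  i <- 1L
  for (L in lengths_desc) {
    while (i <= nrow(v) && v$length[i] >= L) {
      lo <- max(0L, v$place_start[i]); hi <- min(lb, v$place_start[i] + v$length[i])
      if (hi > lo) covered[(lo + 1L):hi] <- TRUE
      i <- i + 1L
    }
    if (sum(covered) >= frac * lb) return(as.integer(L))
  }
  0L
}

#' Assembly error rate
#'
#' Total errors divided by total contig length, where errors are the
#' mismatches of all valid contigs plus the full lengths of invalid contigs.
#'
#' @param contigs Output of [valid_contigs()].
#' @return Error rate in `[0, 1]`; 0 when there are no contigs.
#' @export
error_rate <- function(contigs) {
  if (!nrow(contigs)) return(0)
  total <- sum(contigs$length)
  errs <- sum(contigs$mismatches[contigs$valid]) +
    sum(contigs$length[!contigs$valid])
  errs / total
}

#' Length-weighted dissimilarity to the reference
#'
#' Contigs with reference similarity below `min_sim` are excluded (they
#' typically stem from inserted sequence absent from the reference); the
#' dissimilarity is the length-weighted mean mismatch fraction of the
#' retained contigs' best placements.
#'
#' @param contigs Contigs tibble.
#' @param reference_block_seq The reference (not target) block sequence.
#' @param min_sim Minimal similarity for inclusion (default 0.75).
#' @return Dissimilarity in `[0, 1]`; `NA` when no contig passes the filter.
#' @export
dissimilarity <- function(contigs, reference_block_seq, min_sim = 0.75) {
  if (!nrow(contigs)) return(NA_real_)
  pl <- map(contigs$seq, place_contig, block_seq = reference_block_seq)
  mmf <- map_dbl(pl, "mm_frac")
  keep <- (1 - mmf) >= min_sim
  if (!any(keep)) return(NA_real_)
  sum(mmf[keep] * contigs$length[keep]) / sum(contigs$length[keep])
}

#' Count error-free recovered insertions per length bin
#'
#' An insertion is recovered when some contig contains the full inserted
#' sequence with zero mismatches (either strand).
#'
#' @param contigs Contigs tibble.
#' @param truth Truth list from [mutate_target()].
#' @param length_bins Breaks for binning insertion lengths.
#' @return A tibble with `bin`, `total`, `recovered`.
#' @export
insertion_recovery <- function(contigs, truth,
                               length_bins = c(100, 250, 500, 1000, 2000, Inf)) {
  ins <- truth$insertions
  if (is.null(ins) || !nrow(ins)) {
    return(tibble(bin = character(0), total = integer(0), recovered = integer(0)))
  }
  hay <- c(contigs$seq, revcomp(contigs$seq))
  rec <- map_lgl(ins$seq, function(s)
    any(stringi::stri_detect_fixed(hay, s)))
  bins <- cut(ins$length, breaks = unique(c(0, length_bins)), right = FALSE)
  out <- tibble(bin = as.character(bins), length = ins$length, recovered = rec)
  out <- summarise(group_by(out, .data$bin),
                   total = n(), recovered = sum(.data$recovered),
                   .groups = "drop")
  out
}

#' Evaluate a block assembly against its true sequence
#'
#' @param contigs Contigs tibble for one block.
#' @param target_block_seq True block sequence.
#' @param reference_block_seq Optional reference block sequence for
#'   dissimilarity.
#' @param max_mm_frac Validity threshold.
#' @return One-row tibble: `n50`, `err_rate`, `diss`, `valid_contigs`,
#'   `invalid_contigs`.
#' @export
evaluate_block <- function(contigs, target_block_seq,
                           reference_block_seq = NULL, max_mm_frac = 0.10) {
  vc <- valid_contigs(contigs, target_block_seq, max_mm_frac)
  tibble(
    n50 = block_n50(vc, target_block_seq),
    err_rate = error_rate(vc),
    diss = if (is.null(reference_block_seq)) NA_real_
      else dissimilarity(contigs, reference_block_seq),
    valid_contigs = sum(vc$valid),
    invalid_contigs = sum(!vc$valid)
  )
}

#' Evaluate per-block assemblies and average over blocks
#'
#' `avgN50`, `avgERR` and `avgDISS` are unweighted means over blocks.
#'
#' @param contigs Contigs tibble with a `block` column.
#' @param blocks Blocks tibble from [partition_blocks()].
#' @param target Target genome string (block sequences are substrings unless
#'   `block_seqs` is given).
#' @param block_seqs Optional named list of true block sequences.
#' @param reference Optional reference genome for dissimilarity.
#' @param max_mm_frac Validity threshold.
#' @return A list with `per_block` tibble and `summary` (one row:
#'   `avg_n50`, `avg_err`, `avg_diss`).
#' @export
evaluate_blocks <- function(contigs, blocks, target = NULL, block_seqs = NULL,
                            reference = NULL, max_mm_frac = 0.10) {
  per <- map(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    ctg <- contigs[contigs$block == b$block, , drop = FALSE]
    tseq <- if (!is.null(block_seqs)) block_seqs[[i]]
      else substring(target, b$start + 1L, b$end)
    rseq <- if (is.null(reference)) NULL
      else substring(reference, b$start + 1L, b$end)
    ev <- evaluate_block(ctg, tseq, rseq, max_mm_frac)
    ev$block <- b$block
    ev
  })
  per <- bind_rows(per)
  list(per_block = per,
       summary = tibble(avg_n50 = mean(per$n50),
                        avg_err = mean(per$err_rate),
                        avg_diss = mean(per$diss, na.rm = TRUE)))
}
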
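#' Generate a random reference sequence
#'
#' I.i.d. bases at a given GC content; a stand-in for a real chromosome when
#' exercising the assembler on synthetic data.
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A single upper-case DNA string.
#' @examples
#' random_reference(50, seed = 1)
#' @export
random_reference <- function(length, gc = 0.5, seed = 1L) {
  if (length < 1) abort("`length` must be at least 1")
  withr_seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Mutate a reference into a target genome with recorded truth
#'
#' Introduces SNPs, micro-indels and long novel insertions into a reference
#' sequence, emulating a diverged strain of the reference. Every event is
#' recorded with exact coordinates so downstream evaluation can score
#' assemblies against the truth.
#'
#' @param reference Reference DNA string.
#' @param snp_rate Per-base substitution probability in `[0, 1)`.
#' @param indel_rate Per-base micro-indel probability (events of 1-5 bp).
#' @param insertions A tibble/data.frame with columns `count` and `length`
#'   (novel insertions of `length >= 100` bases each), or `NULL`.
#' @param seed Integer seed.
#' @param min_gap Minimal distance in bases kept between placed events.
#' @return A list with elements `target` (mutated sequence), and `truth`, a
#'   list holding `snps`, `indels`, `insertions` tibbles and `map`, the
#'   reference-to-target segment coordinate map (0-based half-open intervals).
#' @examples
#' mt <- mutate_target(random_reference(2000, seed = 1), snp_rate = 0.005,
#'                     seed = 2)
#' nrow(mt$truth$snps)
#' @export
mutate_target <- function(reference, snp_rate = 0, indel_rate = 0,
                          insertions = NULL, seed = 1L, min_gap = 10L) {
  if (snp_rate < 0 || snp_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    abort("rates must lie in [0, 1)")
  withr_seed(seed)
  L <- nchar(reference)
  bases <- c("A", "C", "G", "T")

  # --- place events on the reference, non-overlapping ------------------------
  n_snp <- rbinom(1, L, snp_rate)
  n_ind <- rbinom(1, L, indel_rate)
  ins_spec <- if (is.null(insertions)) integer(0) else
    rep(as.integer(insertions$length), times = as.integer(insertions$count))
  if (any(ins_spec < 100L))
    abort("novel insertions must be at least 100 bp long")

  # sample distinct positions with spacing for indels/insertions
  n_events <- n_snp + n_ind + length(ins_spec)
  if (n_events > floor(L / (min_gap + 6L)))
    abort("requested events exceed placeable capacity of the reference")
  pos <- sort(sample.int(L, n_events))
  # enforce min_gap by dropping crowded positions and resampling once
  for (it in 1:20) {
    ok <- c(TRUE, diff(pos) > min_gap + 5L)
    if (all(ok)) break
    need <- sum(!ok)
    pos <- sort(unique(c(pos[ok], sample.int(L, need))))
    if (length(pos) < n_events) pos <- sort(unique(c(pos, sample.int(L, n_events - length(pos)))))
    pos <- pos[seq_len(min(length(pos), n_events))]
  }
  ok <- c(TRUE, diff(pos) > min_gap + 5L)
  pos <- pos[ok][seq_len(min(sum(ok), n_events))]
  if (length(pos) < n_events) abort("requested events exceed placeable capacity of the reference")
  pos <- sample(pos)          # random assignment of positions to event kinds
  snp_pos <- sort(head(pos, n_snp))
  ind_pos <- sort(head(tail(pos, -n_snp), n_ind))
  ins_pos <- sort(tail(pos, length(ins_spec)))

  snps <- tibble(pos = snp_pos - 1L,
                 ref_base = if (length(snp_pos))
                   substring(reference, snp_pos, snp_pos) else character(0))
  snps$alt_base <- map_chr(snps$ref_base, function(b)
    sample(setdiff(bases, b), 1))

  indels <- tibble(pos = ind_pos - 1L,
                   type = sample(c("ins", "del"), length(ind_pos), replace = TRUE),
                   len = sample(1:5, length(ind_pos), replace = TRUE))
  indels$seq <- if (nrow(indels)) ifelse(
    indels$type == "ins",
    vapply(indels$len, function(l) paste(sample(bases, l, replace = TRUE), collapse = ""),
           character(1)),
    substring(reference, ind_pos + 1L, ind_pos + indels$len)) else character(0)
  # deletions must not run over the sequence end or into the next event
  keep <- !(indels$type == "del" & (indels$pos + indels$len) >= L)
  indels <- indels[keep, , drop = FALSE]

  ins <- tibble(ref_pos = ins_pos - 1L,
                length = if (length(ins_spec)) sample(ins_spec) else integer(0))
  if (nrow(ins)) {
    ins$seq <- vapply(ins$length, function(l)
      paste(sample(bases, l, replace = TRUE, prob = c(.3, .2, .2, .3)), collapse = ""),
      character(1))
  } else ins$seq <- character(0)

  # --- apply events left to right, building the coordinate map ---------------
  events <- bind_rows(
    if (nrow(snps)) tibble(pos = snps$pos, kind = "snp", len = 1L, seq = snps$alt_base),
    if (nrow(indels)) tibble(pos = indels$pos, kind = paste0("micro_", indels$type),
                             len = indels$len, seq = indels$seq),
    if (nrow(ins)) tibble(pos = ins$ref_pos, kind = "insertion",
                          len = ins$length, seq = ins$seq)
  )
  if (is.null(events) || !nrow(events)) {
    return(list(target = reference,
                truth = list(snps = snps, indels = indels,
                             insertions = mutate(ins, target_pos = integer(0)),
                             map = tibble(ref_start = 0L, ref_end = L,
                                          target_start = 0L, target_end = L))))
  }
  events <- arrange(events, .data$pos)

  out <- character(0)
  map <- list()
  cur_ref <- 0L      # 0-based position in reference already consumed
  cur_tgt <- 0L
  ins_target_pos <- integer(0)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$pos > cur_ref) {
      seg <- substring(reference, cur_ref + 1L, e$pos)
      out <- c(out, seg)
      map[[length(map) + 1L]] <- c(cur_ref, e$pos, cur_tgt, cur_tgt + nchar(seg))
      cur_tgt <- cur_tgt + nchar(seg)
      cur_ref <- e$pos
    }
    if (e$kind == "snp") {
      out <- c(out, e$seq)
      cur_ref <- cur_ref + 1L
      cur_tgt <- cur_tgt + 1L
    } else if (e$kind == "micro_ins" || e$kind == "insertion") {
      if (e$kind == "insertion") ins_target_pos <- c(ins_target_pos, cur_tgt)
      out <- c(out, e$seq)
      cur_tgt <- cur_tgt + e$len
    } else { # micro_del
      cur_ref <- cur_ref + e$len
    }
  }
  if (cur_ref < L) {
    seg <- substring(reference, cur_ref + 1L, L)
    out <- c(out, seg)
    map[[length(map) + 1L]] <- c(cur_ref, L, cur_tgt, cur_tgt + nchar(seg))
    cur_tgt <- cur_tgt + nchar(seg)
  }
  target <- paste(out, collapse = "")
  map <- do.call(rbind, map)
  colnames(map) <- c("ref_start", "ref_end", "target_start", "target_end")
  map <- as_tibble(map)
  ins$target_pos <- ins_target_pos

  list(target = target,
       truth = list(snps = snps, indels = indels, insertions = ins, map = map))
}

#' Simulate error-bearing short reads at a given depth
#'
#' Uniform-coverage substitution-error reads (single or paired) from a genome.
#' The read id encodes the truth origin as `sim:<origin_start>:<strand>:<pair
#' index>:<serial>` (0-based origin of the read on the genome's forward
#' strand), so evaluation never needs a separate truth file.
#'
#' @param genome DNA string to sequence.
#' @param depth Expected sequencing depth (fold coverage), > 0.
#' @param read_len Read length in bases (<= genome length).
#' @param error_rate Per-base substitution error probability.
#' @param paired If `TRUE`, reads come in innie pairs with insert size drawn
#'   from `Normal(insert_mu, insert_sd)`.
#' @param insert_mu,insert_sd Mean and standard deviation of the outer insert
#'   size (bases) in paired mode; `insert_mu` must be at least `2 * read_len`.
#' @param seed Integer seed; identical seeds give identical read sets.
#' @param base_quality Constant Phred quality assigned to every base.
#' @return A reads tibble with columns `id`, `seq`, `qual` (list of integer
#'   Phred values), `mate_id`, `insert_size`, `insert_sd`, plus truth columns
#'   `origin` (0-based start on the genome) and `strand`.
#' @examples
#' g <- random_reference(1000, seed = 1)
#' rd <- simulate_reads(g, depth = 5, read_len = 80, seed = 2)
#' nrow(rd)  # round(5 * 1000 / 80)
#' @export
simulate_reads <- function(genome, depth, read_len = 80L, error_rate = 0,
                           paired = FALSE, insert_mu = 500L, insert_sd = 30L,
                           seed = 1L, base_quality = 35L) {
  G <- nchar(genome)
  if (depth <= 0) abort("`depth` must be positive")
  if (read_len > G) abort("`read_len` must not exceed the genome length")
  if (paired && insert_mu < 2L * read_len)
    abort("`insert_mu` must be at least twice the read length in paired mode")
  withr_seed(seed)

  n_reads <- round(depth * G / read_len)
  if (paired) {
    n_pairs <- max(1L, round(n_reads / 2))
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mu, insert_sd)),
                     2L * read_len), G)
    frag_start <- floor(runif(n_pairs, 0, G - ins + 1))     # 0-based
    r1_start <- frag_start
    r2_start <- frag_start + ins - read_len
    flip <- runif(n_pairs) < 0.5   # which mate is the forward one
    starts <- c(ifelse(flip, r1_start, r2_start),
                ifelse(flip, r2_start, r1_start))
    strands <- c(ifelse(flip, "+", "-"), ifelse(flip, "-", "+"))
    pair_index <- rep(1:2, each = n_pairs)
    serial <- rep(seq_len(n_pairs), 2L)
    ids <- sprintf("sim:%d:%s:%d:%06d/%d", starts, strands, pair_index,
                   serial, pair_index)
    mate <- sprintf("sim:%d:%s:%d:%06d/%d",
                    c(starts[(n_pairs + 1):(2 * n_pairs)], starts[1:n_pairs]),
                    c(strands[(n_pairs + 1):(2 * n_pairs)], strands[1:n_pairs]),
                    c(rep(2L, n_pairs), rep(1L, n_pairs)),
                    serial, c(rep(2L, n_pairs), rep(1L, n_pairs)))
    insert_size <- rep(as.integer(insert_mu), 2L * n_pairs)
    insert_sdv <- rep(as.integer(insert_sd), 2L * n_pairs)
  } else {
    starts <- floor(runif(n_reads, 0, G - read_len + 1))
    strands <- ifelse(runif(n_reads) < 0.5, "+", "-")
    serial <- seq_len(n_reads)
    ids <- sprintf("sim:%d:%s:0:%06d", starts, strands, serial)
    mate <- rep(NA_character_, n_reads)
    insert_size <- rep(NA_integer_, n_reads)
    insert_sdv <- rep(NA_integer_, n_reads)
  }

  seqs <- substring(genome, starts + 1L, starts + read_len)
  # substitution errors
  if (error_rate > 0) {
    n_err <- rbinom(length(seqs), read_len, error_rate)
    idx <- which(n_err > 0)
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
      s <- strsplit(seqs[i], "")[[1]]
      at <- sample.int(read_len, n_err[i])
      s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1), character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  }
  minus <- strands == "-"
  seqs[minus] <- revcomp(seqs[minus])

  tibble(
    id = ids, seq = seqs,
    qual = rep(list(rep(as.integer(base_quality), read_len)), length(seqs)),
    mate_id = mate,
    insert_size = insert_size, insert_sd = insert_sdv,
    origin = as.integer(starts), strand = strands
  )
}

#' Read origins overlapping truth insertions
#'
#' Splits a simulated read set into reads that overlap any novel insertion of
#' the truth (by their recorded origin on the target) and reads that do not.
#' Emulates the partition into mappable reads and left-over reads produced by
#' aligning against the reference: reads carrying inserted sequence fail to
#' align.
#'
#' @param reads Simulated reads tibble (with `origin` column, target
#'   coordinates).
#' @param truth Truth list from [mutate_target()].
#' @param read_len Read length.
#' @param margin Extra bases around each insertion also treated as unmappable.
#' @return A list with `mapped` and `leftover` reads tibbles; `mapped` gains a
#'   `ref_start` column (0-based reference coordinate of the read origin).
#' @export
split_by_insertions <- function(reads, truth, read_len, margin = 0L) {
  ins <- truth$insertions
  ov <- rep(FALSE, nrow(reads))
  if (!is.null(ins) && nrow(ins)) {
    for (i in seq_len(nrow(ins))) {
      s <- ins$target_pos[i] - margin
      e <- ins$target_pos[i] + ins$length[i] + margin
      ov <- ov | (reads$origin < e & (reads$origin + read_len) > s)
    }
  }
  mapped <- reads[!ov, , drop = FALSE]
  # target -> reference coordinate via the segment map
  m <- truth$map
  ref_start <- rep(NA_integer_, nrow(mapped))
  for (i in seq_len(nrow(m))) {
    in_seg <- mapped$origin >= m$target_start[i] & mapped$origin < m$target_end[i]
    ref_start[in_seg] <- mapped$origin[in_seg] - m$target_start[i] + m$ref_start[i]
  }
  mapped$ref_start <- ref_start
  mapped <- mapped[!is.na(ref_start), , drop = FALSE]
  list(mapped = mapped, leftover = reads[ov, , drop = FALSE])
}
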
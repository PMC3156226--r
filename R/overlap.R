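#' Build an exact-kmer index over a read set
#'
#' Every kmer not containing `N` is indexed under its canonical key (the
#' lexicographic minimum of the kmer and its reverse complement), recording
#' the read, the 0-based offset of the kmer on the read's forward strand, and
#' whether the forward kmer equals the canonical key (`strand == "F"`) or its
#' reverse complement (`"R"`). With `single_strand = TRUE` in the config,
#' forward kmers are indexed verbatim and no reverse-complement pairing
#' occurs.
#'
#' @param reads Reads tibble (columns `id`, `seq`).
#' @param k Kmer length, `4 <= k <=` shortest read length.
#' @param single_strand Disable canonical (double-stranded) keying.
#' @return A list of class `kmer_index` with the occurrence tibble (`kmer`,
#'   `read`, `offset`, `strand`), `k`, and the read length lookup.
#' @examples
#' idx <- index_kmers(tibble::tibble(id = "r1", seq = "ACGTACGT"), k = 4)
#' idx$occ
#' @export
index_kmers <- function(reads, k, single_strand = FALSE) {
  k <- as.integer(k)
  if (k < 4L) abort("`k` must be at least 4")
  if (nrow(reads) && k > min(nchar(reads$seq)))
    abort("`k` exceeds the shortest read length")
  occ_l <- map2(reads$id, reads$seq, function(id, s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    km <- substring(s, 1:n, k:(k + n - 1L))
    keep <- !grepl("[^ACGT]", km)
    if (!any(keep)) return(NULL)
    tibble(kmer = km[keep], read = id, offset = which(keep) - 1L)
  })
  occ <- bind_rows(occ_l)
  if (!nrow(occ)) {
    occ <- tibble(kmer = character(0), read = character(0),
                  offset = integer(0), strand = character(0))
  } else if (single_strand) {
    occ$strand <- "F"
  } else {
    rc <- revcomp(occ$kmer)
    is_f <- occ$kmer <= rc
    occ$strand <- ifelse(is_f, "F", "R")
    occ$kmer <- ifelse(is_f, occ$kmer, rc)
  }
  structure(list(occ = occ, k = k,
                 read_len = setNames(nchar(reads$seq), reads$id),
                 single_strand = isTRUE(single_strand)),
            class = "kmer_index")
}

#' Candidate read pairs sharing an identical kmer
#'
#' Expands the kmer index into the set of read pairs sharing at least one
#' identical kmer (on either strand unless single-stranded). Each pair is
#' reported once per relative orientation and offset-difference diagonal;
#' self-pairs are excluded. The diagonal is the 0-based start of the second
#' read (oriented) in the first read's coordinates, with the pair ordered so
#' that `read_a < read_b` lexicographically.
#'
#' @param index A `kmer_index`.
#' @param index_b Optional second `kmer_index`; when given, candidates bridge
#'   the two read pools (used for left-over recruitment) instead of pairing
#'   within one pool.
#' @param max_occ Kmers with more occurrences than this are skipped.
#' @return A tibble with columns `read_a`, `read_b`, `orient`, `diag`.
#' @export
candidate_pairs <- function(index, index_b = NULL, max_occ = 100L) {
  occ <- index$occ
  if (!is.null(index_b) && index_b$k != index$k)
    abort("the two indexes must share the same kmer size")
  k <- index$k
  lens <- c(index$read_len, if (!is.null(index_b)) index_b$read_len)

  trim <- function(o) {
    cnt <- table(o$kmer)
    o[o$kmer %in% names(cnt)[cnt <= max_occ], , drop = FALSE]
  }
  empty <- tibble(read_a = character(0), read_b = character(0),
                  orient = character(0), diag = integer(0))
  if (is.null(index_b)) {
    occ <- trim(occ)
    if (!nrow(occ)) return(empty)
    j <- inner_join(occ, occ, by = "kmer", suffix = c("_a", "_b"),
                    relationship = "many-to-many")
    j <- j[j$read_a < j$read_b, , drop = FALSE]
  } else {
    occ_b <- trim(index_b$occ)
    occ <- trim(occ)
    if (!nrow(occ) || !nrow(occ_b)) return(empty)
    j <- inner_join(occ, occ_b, by = "kmer", suffix = c("_a", "_b"),
                    relationship = "many-to-many")
    j <- j[j$read_a != j$read_b, , drop = FALSE]
    swap <- j$read_a > j$read_b
    if (any(swap)) {
      tmp_r <- j$read_a[swap]; j$read_a[swap] <- j$read_b[swap]; j$read_b[swap] <- tmp_r
      tmp_o <- j$offset_a[swap]; j$offset_a[swap] <- j$offset_b[swap]; j$offset_b[swap] <- tmp_o
      tmp_s <- j$strand_a[swap]; j$strand_a[swap] <- j$strand_b[swap]; j$strand_b[swap] <- tmp_s
    }
  }
  if (!nrow(j)) return(empty)
  same <- j$strand_a == j$strand_b
  lb <- unname(lens[j$read_b])
  diag <- ifelse(same, j$offset_a - j$offset_b,
                 j$offset_a - (lb - k - j$offset_b))
  out <- tibble(read_a = j$read_a, read_b = j$read_b,
                orient = ifelse(same, "F", "R"), diag = as.integer(diag))
  distinct(out)
}

# Gap-free alignment of candidate (read_a, read_b, orient, diag) rows.
# Returns the qualifying alignments (overlap length >= min_overlap, or
# containment) with at most max_mismatches mismatches, one row per candidate
# diagonal; no per-pair deduplication here.
align_candidates <- function(cands, seqs, cfg) {
  empty <- tibble(read_a = character(0), read_b = character(0),
                  kind = character(0), orient = character(0),
                  a_start = integer(0), a_end = integer(0),
                  b_start = integer(0), b_end = integer(0),
                  length = integer(0), mismatches = integer(0),
                  score = numeric(0), end_a = character(0),
                  end_b = character(0), diag = integer(0),
                  container = character(0), contained = character(0),
                  c_start = integer(0))
  if (!nrow(cands)) return(empty)
  lens <- setNames(nchar(seqs), names(seqs))
  la <- unname(lens[cands$read_a])
  lb <- unname(lens[cands$read_b])
  d <- cands$diag
  as0 <- pmax(0L, d)
  ae0 <- pmin(la, d + lb)
  len <- ae0 - as0
  a_full <- as0 == 0L & ae0 == la
  b_full <- (as0 - d) == 0L & (ae0 - d) == lb
  keep <- len >= 1L & (len >= cfg$min_overlap | a_full | b_full)
  if (!any(keep)) return(empty)
  cands <- cands[keep, , drop = FALSE]
  la <- la[keep]; lb <- lb[keep]; d <- d[keep]
  as0 <- as0[keep]; ae0 <- ae0[keep]; len <- len[keep]
  a_full <- a_full[keep]; b_full <- b_full[keep]

  sub_a <- substring(seqs[cands$read_a], as0 + 1L, ae0)
  b_seq <- seqs[cands$read_b]
  is_r <- cands$orient == "R"
  b_seq[is_r] <- revcomp(b_seq[is_r])
  sub_b <- substring(b_seq, as0 - d + 1L, ae0 - d)
  mm <- count_mismatches_vec(sub_a, sub_b)
  ok <- mm <= cfg$max_mismatches
  if (!any(ok)) return(empty)

  cands <- cands[ok, , drop = FALSE]
  la <- la[ok]; lb <- lb[ok]; d <- d[ok]
  as0 <- as0[ok]; ae0 <- ae0[ok]; len <- len[ok]; mm <- mm[ok]
  a_full <- a_full[ok]; b_full <- b_full[ok]

  bs_or <- as0 - d
  be_or <- ae0 - d
  bs <- ifelse(cands$orient == "F", bs_or, lb - be_or)
  be <- ifelse(cands$orient == "F", be_or, lb - bs_or)
  kind <- ifelse(a_full | b_full, "containment", "overlap")
  end_a <- ifelse(kind == "containment", NA_character_,
                  ifelse(as0 > 0L, "R", "L"))
  end_b_or <- ifelse(as0 > 0L, "L", "R")   # end of oriented b involved
  end_b <- ifelse(kind == "containment", NA_character_,
                  ifelse(cands$orient == "F", end_b_or, other_end(end_b_or)))
  # containment bookkeeping: prefer the shorter read as contained; equal
  # lengths fall back to read_b
  contained <- ifelse(kind != "containment", NA_character_,
                      ifelse(a_full & (!b_full | la <= lb),
                             cands$read_a, cands$read_b))
  container <- ifelse(kind != "containment", NA_character_,
                      ifelse(contained == cands$read_a, cands$read_b, cands$read_a))
  # start of the contained read inside the container, container coordinates
  c_start <- ifelse(kind != "containment", NA_integer_,
                    ifelse(contained == cands$read_b, as0,
                           ifelse(cands$orient == "F", bs_or, lb - be_or)))
  # when a is contained in b and orient is R, a occupies b_or [bs_or, be_or);
  # in b's own frame that is [lb - be_or, lb - bs_or) -- equal to bs above
  c_start <- ifelse(kind == "containment" & contained == cands$read_a,
                    bs, c_start)

  tibble(read_a = cands$read_a, read_b = cands$read_b, kind = kind,
         orient = cands$orient,
         a_start = as0, a_end = ae0, b_start = as.integer(bs),
         b_end = as.integer(be), length = len, mismatches = as.integer(mm),
         score = (len - mm) * cfg$match_score + mm * cfg$mismatch_penalty,
         end_a = end_a, end_b = end_b, diag = as.integer(d),
         container = container, contained = contained,
         c_start = as.integer(c_start))
}

# Keep the single best alignment per (read_a, read_b, orient):
# highest score, then longest, then smallest diagonal.
dedup_alignments <- function(aln) {
  if (!nrow(aln)) return(aln)
  aln <- arrange(aln, .data$read_a, .data$read_b, .data$orient,
                 dplyr::desc(.data$score), dplyr::desc(.data$length), .data$diag)
  distinct(aln, .data$read_a, .data$read_b, .data$orient, .keep_all = TRUE)
}

#' Best gap-free overlap or containment alignment between two reads
#'
#' Scans every diagonal of the (optionally reverse-complemented) read pair
#' and returns the highest-scoring gap-free suffix-prefix overlap of length at
#' least `min_len`, or full-length containment, with at most `max_mm`
#' mismatches. Ties break by longer alignment, then smaller diagonal.
#'
#' @param read_a,read_b Named character: one DNA string each, or two rows of a
#'   reads tibble.
#' @param orient `"F"` (as given) or `"R"` (align `read_b`'s reverse
#'   complement).
#' @param min_len Minimal overlap length.
#' @param max_mm Maximal mismatch count.
#' @param config Optional `asm_config` for scoring (defaults used otherwise).
#' @return A one-row alignment tibble, or `NULL` when no alignment qualifies.
#' @examples
#' align_overlap(c(a = "ACGTACGT"), c(b = "TACGTAAA"), min_len = 5, max_mm = 0)
#' @export
align_overlap <- function(read_a, read_b, orient = "F", min_len = 25L,
                          max_mm = 2L, config = NULL) {
  if (is.data.frame(read_a)) read_a <- setNames(read_a$seq, read_a$id)
  if (is.data.frame(read_b)) read_b <- setNames(read_b$seq, read_b$id)
  if (is.null(names(read_a))) names(read_a) <- "read_a"
  if (is.null(names(read_b))) names(read_b) <- "read_b"
  cfg <- config %||% assembly_config()
  cfg$min_overlap <- as.integer(min_len)
  cfg$max_mismatches <- as.integer(max_mm)
  la <- nchar(read_a); lb <- nchar(read_b)
  if (la < 1L || lb < 1L) abort("reads must be non-empty")
  seqs <- c(read_a, read_b)
  ids <- sort(names(seqs))
  a_first <- names(read_a) == ids[1]
  cands <- tibble(read_a = ids[1], read_b = ids[2],
                  orient = orient,
                  diag = seq.int(-(nchar(seqs[[ids[2]]]) - 1L),
                                 nchar(seqs[[ids[1]]]) - 1L))
  aln <- align_candidates(cands, seqs, cfg)
  if (!nrow(aln)) return(NULL)
  if (!a_first) {
    # report coordinates with the caller's argument order
    aln <- swap_alignment(aln, lens = setNames(nchar(seqs), names(seqs)))
  }
  aln <- arrange(aln, dplyr::desc(.data$score), dplyr::desc(.data$length), .data$diag)
  aln[1, , drop = FALSE]
}

# Swap the roles of read_a and read_b in an alignment tibble.
swap_alignment <- function(aln, lens) {
  la <- unname(lens[aln$read_a]); lb <- unname(lens[aln$read_b])
  new_diag <- ifelse(aln$orient == "F", -aln$diag, lb - la + aln$diag)
  tibble(read_a = aln$read_b, read_b = aln$read_a, kind = aln$kind,
         orient = aln$orient,
         a_start = aln$b_start, a_end = aln$b_end,
         b_start = aln$a_start, b_end = aln$a_end,
         length = aln$length, mismatches = aln$mismatches, score = aln$score,
         end_a = aln$end_b, end_b = aln$end_a, diag = as.integer(new_diag),
         container = aln$container, contained = aln$contained,
         c_start = aln$c_start)
}

#' Compute all qualifying overlap alignments within a read pool
#'
#' Kmer indexing, candidate-pair detection and gap-free verification in one
#' pass; each call counts as one overlap-computation pass for the named pool
#' tag (see [overlap_pass_counts()]).
#'
#' @param reads Reads tibble.
#' @param config An `asm_config`.
#' @param tag Counter tag naming the pool (`"local"`, `"leftover"`, ...).
#' @return Alignment tibble (one best alignment per read pair and
#'   orientation).
#' @export
compute_overlaps <- function(reads, config = assembly_config(), tag = "local") {
  bump_counter(tag)
  if (nrow(reads) < 2L)
    return(align_candidates(tibble(read_a = character(0), read_b = character(0),
                                   orient = character(0), diag = integer(0)),
                            setNames(reads$seq, reads$id), config))
  idx <- index_kmers(reads, config$kmer_size, config$single_strand)
  cands <- candidate_pairs(idx, max_occ = config$max_kmer_occ)
  aln <- align_candidates(cands, setNames(reads$seq, reads$id), config)
  dedup_alignments(aln)
}
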
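#' Load sequencing reads from FASTA or FASTQ
#'
#' Parses a read file into the reads tibble used throughout the package.
#' Sequences are upper-cased and RNA `U` is mapped to `T`. Mate links are
#' recovered from `/1` and `/2` read-id suffixes.
#'
#' @param path File path.
#' @param format `"fasta"` or `"fastq"` (default guessed from the extension).
#' @param insert_size,insert_sd Insert-size expectation attached to paired
#'   reads (the formats themselves carry none).
#' @return A tibble with columns `id`, `seq`, `qual` (list column of integer
#'   Phred values, `NULL` entries for FASTA), `mate_id`, `insert_size`,
#'   `insert_sd`.
#' @export
load_reads <- function(path, format = NULL,
                       insert_size = NA_integer_, insert_sd = NA_integer_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  format <- format %||%
    (if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta")
  if (!format %in% c("fasta", "fastq")) abort("`format` must be fasta or fastq")
  if (file.size(path) == 0L)
    return(tibble(id = character(0), seq = character(0), qual = list(),
                  mate_id = character(0), insert_size = integer(0),
                  insert_sd = integer(0)))
  validate_read_file(path, format)
  # BStringSet first: RNA-style U and lowercase letters survive parsing and
  # are normalised below
  if (format == "fastq") {
    x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as(Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities), "IntegerList")
    qual <- as.list(qual)
  } else {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(list(NULL), length(x))
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    abort(paste0("duplicate read id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- chartr("Uu", "Tt", as.character(x))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs)))
    abort("reads contain characters outside {A,C,G,T,N,U}")
  out <- tibble(id = ids, seq = unname(seqs), qual = qual,
                mate_id = NA_character_,
                insert_size = NA_integer_, insert_sd = NA_integer_)
  pair_reads(out, insert_size, insert_sd)
}

# Light structural validation so malformed records fail with a line number
# (the Biostrings parser's own errors do not carry one).
validate_read_file <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "fastq") {
    if (length(lines) %% 4L != 0L)
      abort(sprintf("parse error near line %d: FASTQ record truncated", length(lines)))
    hdr <- seq(1L, length(lines), by = 4L)
    bad <- hdr[!startsWith(lines[hdr], "@")]
    if (length(bad))
      abort(sprintf("parse error at line %d: expected '@' FASTQ header", bad[1]))
    plus <- hdr + 2L
    bad <- plus[!startsWith(lines[plus], "+")]
    if (length(bad))
      abort(sprintf("parse error at line %d: expected '+' separator", bad[1]))
    lens <- nchar(lines[hdr + 1L]) != nchar(lines[hdr + 3L])
    if (any(lens))
      abort(sprintf("parse error at line %d: sequence/quality length mismatch",
                    hdr[which(lens)[1]] + 3L))
  } else {
    if (!startsWith(lines[1], ">"))
      abort("parse error at line 1: expected '>' FASTA header")
  }
  invisible(TRUE)
}

# Recover symmetric mate links from /1 and /2 id suffixes.
pair_reads <- function(reads, insert_size = NA_integer_, insert_sd = NA_integer_) {
  stem <- sub("/[12]$", "", reads$id)
  sufx <- ifelse(grepl("/1$", reads$id), 1L, ifelse(grepl("/2$", reads$id), 2L, NA_integer_))
  mate_of <- ifelse(sufx == 1L, paste0(stem, "/2"),
                    ifelse(sufx == 2L, paste0(stem, "/1"), NA_character_))
  has_mate <- !is.na(mate_of) & mate_of %in% reads$id
  reads$mate_id <- ifelse(has_mate, mate_of, reads$mate_id)
  if (!all(is.na(insert_size))) {
    reads$insert_size <- ifelse(has_mate & is.na(reads$insert_size),
                                as.integer(insert_size), reads$insert_size)
    reads$insert_sd <- ifelse(has_mate & is.na(reads$insert_sd),
                              as.integer(insert_sd), reads$insert_sd)
  }
  reads
}

#' Write reads to FASTQ
#'
#' @param reads Reads tibble; entries without qualities get constant Phred 35.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  qual <- map2(reads$qual, nchar(reads$seq), function(q, n) {
    if (is.null(q)) rep(35L, n) else q
  })
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$id)
  lines[seq(2, length(lines), 4)] <- reads$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- vapply(qual, function(q)
    rawToChar(as.raw(q + 33L)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load read-to-reference alignments
#'
#' Reads mapped-read records from a SAM file (unmapped records are skipped,
#' `POS` is converted from 1-based to the 0-based `ref_start` used internally)
#' or from a simple TSV dialect with columns
#' `read_id, ref_id, ref_start, strand, edit_distance` (already 0-based).
#'
#' @param path File path.
#' @param dialect `"sam"` or `"tsv"` (guessed from the extension by default).
#' @param reference Optional named character vector of reference sequences;
#'   when supplied, records citing unknown reference names are an error.
#' @return A tibble with columns `read_id`, `ref_id`, `ref_start`, `strand`,
#'   `edit_distance`.
#' @export
load_alignments <- function(path, dialect = NULL, reference = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dialect <- dialect %||%
    (if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv")
  if (dialect == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos"),
                                 tag = "NM")
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    keep <- !bitwAnd(x$flag, 4L) & !is.na(x$pos)
    nm <- x$tag$NM
    if (is.null(nm)) nm <- rep(0L, length(x$qname))
    nm[is.na(nm)] <- 0L
    out <- tibble(read_id = x$qname[keep],
                  ref_id = as.character(x$rname[keep]),
                  ref_start = x$pos[keep] - 1L,
                  strand = ifelse(bitwAnd(x$flag[keep], 16L) > 0L, "-", "+"),
                  edit_distance = as.integer(nm[keep]))
  } else {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
    if (!length(raw))
      return(tibble(read_id = character(0), ref_id = character(0),
                    ref_start = integer(0), strand = character(0),
                    edit_distance = integer(0)))
    parts <- strsplit(raw, "\t| +")
    bad <- which(lengths(parts) < 5L)
    if (length(bad))
      abort(sprintf("parse error at line %d: expected 5 tab-separated fields", bad[1]))
    m <- do.call(rbind, lapply(parts, `[`, 1:5))
    out <- tibble(read_id = m[, 1], ref_id = m[, 2],
                  ref_start = as.integer(m[, 3]), strand = m[, 4],
                  edit_distance = as.integer(m[, 5]))
    if (any(is.na(out$ref_start)) || any(out$ref_start < 0))
      abort("ref_start must be a non-negative integer")
    if (!all(out$strand %in% c("+", "-")))
      abort("strand must be '+' or '-'")
  }
  if (!is.null(reference)) {
    unknown <- setdiff(unique(out$ref_id), names(reference))
    if (length(unknown))
      abort(paste0("alignments cite unknown reference name(s): ",
                   paste(unknown, collapse = ", ")))
  }
  out
}

#' Write alignments in the TSV dialect
#' @param alignments Mapped-read tibble from [load_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  writeLines(sprintf("%s\t%s\t%d\t%s\t%d",
                     alignments$read_id, alignments$ref_id,
                     alignments$ref_start, alignments$strand,
                     alignments$edit_distance), path)
  invisible(path)
}

#' Write contigs to FASTA
#'
#' Standard 60-column wrapped FASTA; the header carries contig length, read
#' count and (if present) block id: `>ctg1 len=130 reads=5 block=2`.
#'
#' @param contigs Contigs tibble (columns `id`, `seq`, optionally `read_path`
#'   list column and `block`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  if (anyDuplicated(contigs$id)) abort("contig ids must be unique")
  if (!nrow(contigs)) {
    file.create(path)
    return(invisible(path))
  }
  hdr <- sprintf(">%s len=%d reads=%d%s",
                 contigs$id, nchar(contigs$seq),
                 if ("read_path" %in% names(contigs)) lengths(contigs$read_path)
                 else rep(0L, nrow(contigs)),
                 if ("block" %in% names(contigs))
                   paste0(" block=", contigs$block) else "")
  x <- Biostrings::DNAStringSet(contigs$seq)
  names(x) <- sub("^>", "", hdr)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Dump a graph to GFA1
#'
#' Overlap graphs are written with one `S` line per read retained after
#' containment reduction (plus contained reads, which only appear in `C`
#' lines), one `L` line per overlap edge (gap-free overlap length as a
#' `<n>M` CIGAR), and one `C` line per containment edge. Path graphs are
#' written with inner edges as segments and real edges as links.
#'
#' @param graph An `overlap_graph` or `path_graph` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_graph <- function(graph, path) {
  lines <- "H\tVN:Z:1.0"
  if (inherits(graph, "overlap_graph")) {
    ov <- graph$edges[graph$edges$kind == "overlap", , drop = FALSE]
    ct <- graph$edges[graph$edges$kind == "containment", , drop = FALSE]
    segs <- graph$vertices
    lines <- c(lines, sprintf("S\t%s\t*\tLN:i:%d", segs$id, segs$length))
    if (nrow(ov)) {
      # orientation of the link follows which read ends meet
      o_a <- ifelse(ov$end_a == "R", "+", "-")
      o_b <- ifelse(ov$orient == "F", "+", "-")
      o_b <- ifelse(ov$end_a == "R", o_b, chartr("+-", "-+", o_b))
      lines <- c(lines, sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                                ov$read_a, o_a, ov$read_b, o_b, ov$length))
    }
    if (nrow(ct)) {
      lines <- c(lines, sprintf("C\t%s\t+\t%s\t%s\t%d\t%dM",
                                ct$container, ct$contained,
                                ifelse(ct$orient == "F", "+", "-"),
                                as.integer(ct$c_start), ct$length))
    }
  } else if (inherits(graph, "path_graph")) {
    lines <- c(lines, sprintf("S\t%s\t*\tLN:i:%d",
                              graph$inner$inner_id, graph$inner$length))
    if (nrow(graph$real)) {
      lines <- c(lines, sprintf("L\t%s\t+\t%s\t+\t0M\tRC:i:0",
                                graph$real$v1, graph$real$v2))
    }
  } else abort("`graph` must be an overlap_graph or path_graph")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFA1 dump back into tibbles
#' @param path GFA file written by [dump_graph()].
#' @return A list with `segments`, `links` and `containments` tibbles.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  f <- substring(lines, 1, 1)
  seg <- strsplit(lines[f == "S"], "\t")
  lnk <- strsplit(lines[f == "L"], "\t")
  cnt <- strsplit(lines[f == "C"], "\t")
  list(
    segments = tibble(
      id = map_chr(seg, 2),
      length = as.integer(sub("LN:i:", "", map_chr(seg, 4)))),
    links = if (length(lnk)) tibble(
      from = map_chr(lnk, 2), from_orient = map_chr(lnk, 3),
      to = map_chr(lnk, 4), to_orient = map_chr(lnk, 5),
      overlap = as.integer(sub("M$", "", map_chr(lnk, 6))))
    else tibble(from = character(0), from_orient = character(0),
                to = character(0), to_orient = character(0),
                overlap = integer(0)),
    containments = if (length(cnt)) tibble(
      container = map_chr(cnt, 2), contained = map_chr(cnt, 4),
      orient = map_chr(cnt, 5), pos = as.integer(map_chr(cnt, 6)),
      overlap = as.integer(sub("M$", "", map_chr(cnt, 7))))
    else tibble(container = character(0), contained = character(0),
                orient = character(0), pos = integer(0), overlap = integer(0))
  )
}
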
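# Shared fixtures and independent oracles used across the suite.

rc <- function(x) stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))

make_reads <- function(seqs) {
  tibble::tibble(id = names(seqs), seq = unname(seqs),
                 qual = rep(list(NULL), length(seqs)),
                 mate_id = NA_character_, insert_size = NA_integer_,
                 insert_sd = NA_integer_)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads tiling a genome at given 0-based starts / lengths / strands
tile_reads <- function(genome, starts, len = 80L, strands = NULL,
                       prefix = "r") {
  seqs <- substring(genome, starts + 1L, starts + len)
  if (!is.null(strands)) seqs[strands == "-"] <- rc(seqs[strands == "-"])
  names(seqs) <- sprintf("%s%03d", prefix, seq_along(starts))
  make_reads(seqs)
}

# Independent brute-force best gap-free overlap/containment alignment:
# scans every diagonal of both orientations with per-character comparison.
brute_best_alignment <- function(sa, sb, min_len, max_mm,
                                 match = 1, mispen = -2,
                                 orients = c("F", "R")) {
  la <- nchar(sa); lb <- nchar(sb)
  best <- NULL
  for (o in orients) {
    b <- if (o == "F") sb else rc(sb)
    for (d in seq(-(lb - 1L), la - 1L)) {
      a0 <- max(0L, d); a1 <- min(la, d + lb)
      len <- a1 - a0
      if (len < 1L) next
      a_full <- a0 == 0L && a1 == la
      b_full <- (a0 - d) == 0L && (a1 - d) == lb
      if (len < min_len && !a_full && !b_full) next
      xs <- strsplit(substring(sa, a0 + 1L, a1), "")[[1]]
      ys <- strsplit(substring(b, a0 - d + 1L, a1 - d), "")[[1]]
      mm <- sum(xs != ys)
      if (mm > max_mm) next
      sc <- (len - mm) * match + mm * mispen
      if (is.null(best) || sc > best$score ||
          (sc == best$score && len > best$length)) {
        best <- list(score = sc, length = len, mismatches = mm,
                     orient = o, diag = d,
                     kind = if (a_full || b_full) "containment" else "overlap")
      }
    }
  }
  best
}

# Independent shared-kmer check for a read pair (both orientations).
brute_shared_kmer <- function(sa, sb, k) {
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    km <- substring(s, 1:n, k:(k + n - 1L))
    km[!grepl("[^ACGT]", km)]
  }
  ka <- kmers(sa)
  out <- c()
  if (length(intersect(ka, kmers(sb)))) out <- c(out, "F")
  if (length(intersect(ka, kmers(rc(sb))))) out <- c(out, "R")
  out
}

# Exhaustive fixpoint oracle for transitive reduction: repeatedly marks every
# edge for which an orientation-consistent two-edge witness with weights at
# least the edge's own exists, deletes all marked edges at once, and repeats
# until no change.
oracle_transitive <- function(edges) {
  repeat {
    n <- nrow(edges)
    if (n < 3L) return(edges)
    # directed views as plain vectors
    from <- c(edges$read_a, edges$read_b)
    fe <- c(edges$end_a, edges$end_b)
    to <- c(edges$read_b, edges$read_a)
    te <- c(edges$end_b, edges$end_a)
    oo <- c(edges$orient, edges$orient)
    ww <- c(edges$length, edges$length)
    id <- c(edges$edge_id, edges$edge_id)
    mark <- logical(n)
    for (t in seq_len(n)) {
      wt <- edges$length[t]
      i1 <- which(from == edges$read_a[t] & fe == edges$end_a[t] &
                    ww >= wt & id != edges$edge_id[t])
      hit <- FALSE
      for (i in i1) {
        j2 <- which(from == to[i] & fe != te[i] & to == edges$read_b[t] &
                      te == edges$end_b[t] & ww >= wt &
                      id != edges$edge_id[t] & id != id[i] &
                      ifelse(oo == oo[i], "F", "R") == edges$orient[t])
        if (length(j2)) { hit <- TRUE; break }
      }
      mark[t] <- hit
    }
    if (!any(mark)) return(edges)
    edges <- edges[!mark, , drop = FALSE]
  }
}

# Independent maximal-unique-path enumerator: extends every edge left and
# right through reads whose two ends each carry exactly one edge, and
# returns the set of chains as canonical read-id strings.
oracle_unique_paths <- function(edges, read_ids) {
  if (!nrow(edges)) return(sort(read_ids))
  endkey <- function(r, e) paste0(r, "#", e)
  cnt <- table(c(endkey(edges$read_a, edges$end_a),
                 endkey(edges$read_b, edges$end_b)))
  degree <- function(r, e) {
    v <- cnt[endkey(r, e)]
    if (is.na(v)) 0L else as.integer(v)
  }
  passth <- function(r) degree(r, "L") == 1L && degree(r, "R") == 1L
  edge_at <- function(r, e, not_id) {
    hit <- which((edges$read_a == r & edges$end_a == e) |
                   (edges$read_b == r & edges$end_b == e))
    hit <- setdiff(hit, not_id)
    if (length(hit)) hit[1] else NA_integer_
  }
  chains <- list()
  used <- logical(nrow(edges))
  for (s in seq_len(nrow(edges))) {
    if (used[s]) next
    # grow in both directions from edge s
    chain_edges <- s
    # walk from read_a side outwards
    grow <- function(r, entry_end, eid_list) {
      repeat {
        if (!passth(r)) break
        nxt <- edge_at(r, if (entry_end == "L") "R" else "L", eid_list)
        if (is.na(nxt) || used[nxt]) break
        eid_list <- c(eid_list, nxt)
        e <- edges[nxt, ]
        if (e$read_a == r) { r <- e$read_b; entry_end <- e$end_b }
        else { r <- e$read_a; entry_end <- e$end_a }
      }
      eid_list
    }
    e0 <- edges[s, ]
    chain_edges <- grow(e0$read_a, e0$end_a, chain_edges)
    chain_edges <- grow(e0$read_b, e0$end_b, chain_edges)
    used[chain_edges] <- TRUE
    # order reads along the chain
    sub <- edges[chain_edges, , drop = FALSE]
    reads <- unique(c(sub$read_a, sub$read_b))
    deg_in <- table(c(sub$read_a, sub$read_b))
    term <- names(deg_in)[deg_in == 1L]
    pure_cycle <- FALSE
    if (!length(term)) {
      knots <- reads[!vapply(reads, passth, logical(1))]
      if (length(knots)) term <- sort(knots)  # lollipop: start at the knot
      else { term <- min(reads); pure_cycle <- TRUE }
    }
    ordered <- term[1]
    cur <- term[1]; prev_edge <- integer(0)
    repeat {
      if (pure_cycle && length(ordered) >= length(reads)) break
      if (!pure_cycle && length(prev_edge) >= nrow(sub)) break
      hit <- which((sub$read_a == cur | sub$read_b == cur))
      hit <- setdiff(hit, prev_edge)
      if (!length(hit)) break
      hit <- hit[order(sub$edge_id[hit])]
      e <- sub[hit[1], ]
      cur <- if (e$read_a == cur) e$read_b else e$read_a
      prev_edge <- c(prev_edge, hit[1])
      ordered <- c(ordered, cur)
    }
    chains[[length(chains) + 1L]] <- ordered
  }
  canon <- vapply(chains, function(x) {
    alt <- rev(x)
    paste(if (paste(x, collapse = ",") <= paste(alt, collapse = ","))
      x else alt, collapse = ",")
  }, character(1))
  iso <- setdiff(read_ids, unique(c(edges$read_a, edges$read_b)))
  sort(c(canon, iso))
}

# Threshold-enumeration oracle for the positional block N50.
oracle_block_n50 <- function(lengths, starts, block_len, frac = 0.5) {
  if (!length(lengths)) return(0L)
  best <- 0L
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    cov <- logical(block_len)
    for (i in which(lengths >= L)) {
      lo <- max(0L, starts[i]); hi <- min(block_len, starts[i] + lengths[i])
      if (hi > lo) cov[(lo + 1L):hi] <- TRUE
    }
    if (sum(cov) >= frac * block_len) return(as.integer(L))
  }
  0L
}

# Random geometric overlap graph over n_reads reads tiled on a genome with a
# possible repeat; edges from the package's aligner (input data), weights =
# lengths. Used as input for reduction oracles.
random_overlap_graph <- function(seed, n_reads = 12L, genome_len = 420L,
                                 with_repeat = TRUE) {
  set.seed(seed)
  g <- random_seq(genome_len)
  if (with_repeat && runif(1) < 0.5) {
    rep_seq <- substring(g, 51, 130)
    g <- paste0(substring(g, 1, 260), rep_seq, substring(g, 341, genome_len))
  }
  starts <- sort(sample.int(nchar(g) - 90L, n_reads)) - 1L
  lens <- sample(60:90, n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(g, starts + 1L, starts + lens)
  seqs[strands == "-"] <- rc(seqs[strands == "-"])
  reads <- make_reads(setNames(seqs, sprintf("g%02d", seq_len(n_reads))))
  cfg <- assembly_config(kmer_size = 8L, min_overlap = 15L, max_mismatches = 0L)
  aln <- compute_overlaps(reads, cfg, tag = "fixture")
  graph <- build_overlap_graph(reads, aln)
  reduce_containments(graph)
}

# Hand-constructed overlap-graph fixture from explicit dovetail edges.
# Each edge: list(a, b, end_a, end_b, orient, diag, len, mm)
fabricate_graph <- function(read_lens, edges) {
  seqs <- vapply(read_lens, function(l) random_seq(l), character(1))
  reads <- make_reads(setNames(seqs, names(read_lens)))
  rows <- lapply(edges, function(e) {
    la <- read_lens[[e$a]]; lb <- read_lens[[e$b]]
    d <- e$diag
    a0 <- max(0L, d); a1 <- min(la, d + lb)
    tibble::tibble(read_a = e$a, read_b = e$b, kind = e$kind %||% "overlap",
                   orient = e$orient, a_start = a0, a_end = a1,
                   b_start = a0 - d, b_end = a1 - d,
                   length = if (is.null(e$len)) a1 - a0 else e$len,
                   mismatches = e$mm %||% 0L,
                   score = (a1 - a0), end_a = e$end_a, end_b = e$end_b,
                   diag = as.integer(d),
                   container = NA_character_, contained = NA_character_,
                   c_start = NA_integer_)
  })
  build_overlap_graph(reads, dplyr::bind_rows(rows))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-copy exact repeat genome used by the repeat-resolution tests.
repeat_genome <- function(total = 10000L, rep_len = 300L, seed = 55L,
                          pos1 = 3001L, pos2 = 6001L) {
  base <- random_reference(total, seed = seed)
  rep_seq <- substring(base, pos1, pos1 + rep_len - 1L)
  paste0(substring(base, 1, pos2 - 1L), rep_seq,
         substring(base, pos2 + rep_len, total))
}

contig_matches_genome <- function(ctg, genome) {
  grepl(ctg, genome, fixed = TRUE) || grepl(rc(ctg), genome, fixed = TRUE)
}
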
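test_that("reference and read simulation are reproducible per seed", {
  expect_equal(random_reference(500, seed = 7), random_reference(500, seed = 7))
  expect_false(random_reference(500, seed = 7) == random_reference(500, seed = 8))
  g <- random_reference(2000, seed = 1)
  r1 <- simulate_reads(g, depth = 5, read_len = 80, error_rate = 0.01, seed = 2)
  r2 <- simulate_reads(g, depth = 5, read_len = 80, error_rate = 0.01, seed = 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_reads(r1, f1); write_reads(r2, f2)
  expect_equal(readLines(f1), readLines(f2))  # byte-identical FASTQ
})

test_that("GC content and sequence boundaries behave", {
  g <- random_reference(100000, gc = 0.5, seed = 3)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / nchar(g)
  expect_lt(abs(gc - 0.5), 0.01)
  expect_equal(nchar(random_reference(1, seed = 4)), 1L)
  expect_true(random_reference(1, seed = 4) %in% c("A", "C", "G", "T"))
})

test_that("read counts follow round(depth * G / read_len)", {
  g <- random_reference(10000, seed = 5)
  rd <- simulate_reads(g, depth = 7.5, read_len = 80, seed = 6)
  expect_equal(nrow(rd), 938L)   # round(7.5 * 10000 / 80)
  # coverage conservation within one read
  expect_lt(abs(sum(nchar(rd$seq)) / nchar(g) - 7.5), 80 / nchar(g) + 1e-9)
})

test_that("error-free reads are exact genome substrings; errors hit the rate", {
  g <- random_reference(3000, seed = 7)
  rd0 <- simulate_reads(g, depth = 3, read_len = 60, error_rate = 0, seed = 8)
  for (i in seq_len(nrow(rd0))) {
    s <- rd0$seq[i]
    expect_true(grepl(s, g, fixed = TRUE) || grepl(rc(s), g, fixed = TRUE))
  }
  rd1 <- simulate_reads(g, depth = 40, read_len = 80, error_rate = 0.01, seed = 9)
  mm <- 0L; tot <- 0L
  for (i in seq_len(nrow(rd1))) {
    s <- if (rd1$strand[i] == "-") rc(rd1$seq[i]) else rd1$seq[i]
    truth <- substring(g, rd1$origin[i] + 1L, rd1$origin[i] + 80L)
    mm <- mm + sum(charToRaw(s) != charToRaw(truth))
    tot <- tot + 80L
  }
  expect_gt(tot, 1e5)
  sigma <- sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(mm / tot - 0.01), 3 * sigma + 1e-6)
})

test_that("paired reads respect insert-size geometry and symmetric pairing", {
  g <- random_reference(5000, seed = 10)
  rd <- simulate_reads(g, depth = 6, read_len = 80, paired = TRUE,
                       insert_mu = 500, insert_sd = 30, seed = 11)
  expect_true(all(!is.na(rd$mate_id)))
  m <- match(rd$mate_id, rd$id)
  expect_equal(rd$id, rd$mate_id[m])       # mate links are symmetric
  ins <- abs((rd$origin[m] + 80) - rd$origin)
  spans <- pmax(rd$origin, rd$origin[m]) + 80 - pmin(rd$origin, rd$origin[m])
  expect_lt(abs(mean(spans) - 500), 15)
  expect_true(all(rd$strand != rd$strand[m]))  # innie orientation
  expect_error(simulate_reads(g, 5, 80, paired = TRUE, insert_mu = 100),
               "twice the read length")
})

test_that("mutate_target applies recorded events exactly", {
  ref <- random_reference(30000, seed = 12)
  mt <- mutate_target(ref, snp_rate = 0.002, indel_rate = 0.0005,
                      insertions = data.frame(count = 2, length = 300),
                      seed = 13)
  tr <- mt$truth
  expect_equal(nrow(tr$insertions), 2L)
  expect_true(all(tr$insertions$length == 300L))
  # coordinate map is consistent: unmodified segments match both sequences
  for (i in seq_len(nrow(tr$map))) {
    m <- tr$map[i, ]
    expect_equal(substring(ref, m$ref_start + 1L, m$ref_end),
                 substring(mt$target, m$target_start + 1L, m$target_end))
  }
  # SNPs: the target carries the alt base at the mapped position
  expect_true(all(tr$snps$ref_base != tr$snps$alt_base))
  # recorded insertions appear verbatim at their target positions
  for (i in seq_len(nrow(tr$insertions))) {
    p <- tr$insertions[i, ]
    expect_equal(substring(mt$target, p$target_pos + 1L, p$target_pos + p$length),
                 p$seq)
  }
  # length accounting
  net_indel <- sum(tr$indels$len[tr$indels$type == "ins"]) -
    sum(tr$indels$len[tr$indels$type == "del"])
  expect_equal(nchar(mt$target),
               nchar(ref) + sum(tr$insertions$length) + net_indel)
})

test_that("identity mutation returns the reference unchanged", {
  ref <- random_reference(2000, seed = 14)
  mt <- mutate_target(ref, 0, 0, NULL, seed = 15)
  expect_equal(mt$target, ref)
  expect_equal(nrow(mt$truth$snps), 0L)
  expect_equal(nrow(mt$truth$insertions), 0L)
})

test_that("SNP counts concentrate around the requested rate", {
  ref <- random_reference(100000, seed = 16)
  mt <- mutate_target(ref, snp_rate = 0.01, seed = 17)
  n <- nrow(mt$truth$snps)
  expect_lt(abs(n - 1000), 3 * sqrt(1000) + 20)
})

test_that("overfull event requests fail loudly", {
  ref <- random_reference(500, seed = 18)
  expect_error(mutate_target(ref, insertions = data.frame(count = 60, length = 100),
                             seed = 19), "capacity")
})

test_that("split_by_insertions separates insertion reads with exact ref coordinates", {
  ref <- random_reference(20000, seed = 20)
  mt <- mutate_target(ref, insertions = data.frame(count = 3, length = 400),
                      seed = 21)
  rd <- simulate_reads(mt$target, depth = 8, read_len = 80, seed = 22)
  sp <- split_by_insertions(rd, mt$truth, 80L)
  expect_equal(nrow(sp$mapped) + nrow(sp$leftover), nrow(rd))
  # leftover reads all touch an insertion; mapped reads map exactly
  ins <- mt$truth$insertions
  touches <- function(o) any(o < ins$target_pos + ins$length & o + 80 > ins$target_pos)
  expect_true(all(vapply(sp$leftover$origin, touches, logical(1))))
  for (i in sample(nrow(sp$mapped), 50)) {
    r <- sp$mapped[i, ]
    s <- if (r$strand == "-") rc(r$seq) else r$seq
    expect_equal(substring(ref, r$ref_start + 1L, r$ref_start + 80L), s)
  }
})
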
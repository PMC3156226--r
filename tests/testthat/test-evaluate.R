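mk_contigs <- function(seqs) {
  tibble::tibble(id = names(seqs), seq = unname(seqs),
                 length = nchar(seqs), read_path = rep(list(character(0)),
                                                       length(seqs)),
                 support = rep(list(integer(0)), length(seqs)),
                 n_reads = 0L)
}

test_that("contig validity follows the 10% mismatch rule with <= semantics", {
  block <- random_seq(1000, seed = 51)
  exact <- substring(block, 101, 400)
  vc <- valid_contigs(mk_contigs(c(c1 = exact)), block)
  expect_true(vc$valid)
  expect_equal(vc$mismatches, 0L)
  expect_equal(vc$place_start, 100L)
  # random unrelated contig is invalid
  junk <- random_seq(200, seed = 52)
  vc2 <- valid_contigs(mk_contigs(c(c1 = junk)), block)
  expect_false(vc2$valid)
  expect_gt(vc2$mm_frac, 0.5)
  # exactly 10.0% mismatches is still valid
  s <- substring(block, 1, 100)
  pos <- seq(5, 95, by = 10)
  for (i in pos) {
    old <- substring(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  vc3 <- valid_contigs(mk_contigs(c(c1 = s)), block)
  expect_equal(vc3$mismatches, 10L)
  expect_true(vc3$valid)
  # reverse-complement placement works
  vc4 <- valid_contigs(mk_contigs(c(c1 = rc(exact))), block)
  expect_true(vc4$valid)
  expect_equal(vc4$place_strand, "-")
})

test_that("block N50 follows the positional coverage definition", {
  block <- random_seq(1000, seed = 53)
  ctg <- mk_contigs(c(a = substring(block, 1, 600),
                      b = substring(block, 651, 950),
                      c = substring(block, 301, 500)))
  vc <- valid_contigs(ctg, block)
  # lengths 600/300/200 non-overlapping enough: 600 alone covers 60%
  expect_equal(block_n50(vc, block), 600L)
  # no valid contigs -> 0
  empty <- valid_contigs(mk_contigs(c(x = random_seq(150, seed = 54))), block)
  expect_equal(block_n50(empty, block), 0L)
  # a single full-length contig -> block length
  full <- valid_contigs(mk_contigs(c(f = block)), block)
  expect_equal(block_n50(full, block), 1000L)
})

test_that("block N50 equals the threshold-enumeration oracle on random sets", {
  set.seed(55)
  for (case in 1:30) {
    block_len <- 1000L
    n <- sample(1:8, 1)
    lens <- sample(50:600, n, replace = TRUE)
    starts <- vapply(lens, function(l) sample(0:(block_len - l), 1), numeric(1))
    vc <- tibble::tibble(length = lens, place_start = as.integer(starts),
                         valid = TRUE)
    got <- block_n50(vc, strrep("A", block_len))
    want <- oracle_block_n50(lens, as.integer(starts), block_len)
    expect_equal(got, want)
  }
})

test_that("error rate matches its printed formula on the worked example", {
  block <- random_seq(1200, seed = 56)
  good <- substring(block, 101, 600)       # 500 bp
  for (i in c(100, 300)) {
    old <- substring(good, i, i)
    substr(good, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  bad <- random_seq(100, seed = 57)
  vc <- valid_contigs(mk_contigs(c(v = good, iv = bad)), block)
  expect_equal(vc$valid, c(TRUE, FALSE))
  expect_equal(error_rate(vc), 102 / 600)
  # all-exact contigs -> 0; only-invalid contigs -> 1
  vc0 <- valid_contigs(mk_contigs(c(v = substring(block, 1, 300))), block)
  expect_equal(error_rate(vc0), 0)
  vc1 <- valid_contigs(mk_contigs(c(iv = bad)), block)
  expect_equal(error_rate(vc1), 1)
  expect_equal(error_rate(vc0[0, ]), 0)
  # invariant under reordering
  expect_equal(error_rate(vc[2:1, ]), error_rate(vc))
})

test_that("dissimilarity is a length-weighted mean over similar contigs", {
  ref <- random_seq(2000, seed = 58)
  c100 <- substring(ref, 101, 200)
  for (i in c(20, 70)) {                   # 2 mismatches in 100 -> 98%
    old <- substring(c100, i, i)
    substr(c100, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  c300 <- substring(ref, 501, 800)
  for (i in seq(12, 300, length.out = 12)) {  # 12 mismatches in 300 -> 96%
    i <- round(i)
    old <- substring(c300, i, i)
    substr(c300, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  d <- dissimilarity(mk_contigs(c(a = c100, b = c300)), ref)
  expect_equal(d, (0.02 * 100 + 0.04 * 300) / 400, tolerance = 1e-9)
  # contigs below 75% similarity are excluded
  d2 <- dissimilarity(mk_contigs(c(a = c100, junk = random_seq(200, seed = 59))),
                      ref)
  expect_equal(d2, 0.02, tolerance = 1e-9)
  expect_equal(dissimilarity(mk_contigs(c(a = substring(ref, 1, 500))), ref), 0)
})

test_that("insertion recovery demands the full inserted sequence, error-free", {
  ref <- random_reference(5000, seed = 60)
  mt <- mutate_target(ref, insertions = data.frame(count = 2, length = 200),
                      seed = 61)
  ins <- mt$truth$insertions
  flank_hit <- paste0("ACGT", ins$seq[1], "TGCA")
  partial <- substring(ins$seq[2], 1, 190)
  ctg <- mk_contigs(c(whole = flank_hit, part = paste0("AA", partial)))
  rec <- insertion_recovery(ctg, mt$truth)
  expect_equal(sum(rec$recovered), 1L)
  # reverse-complement containment counts too
  ctg2 <- mk_contigs(c(rcv = rc(flank_hit)))
  expect_equal(sum(insertion_recovery(ctg2, mt$truth)$recovered), 1L)
})

test_that("per-block evaluation averages unweighted over blocks", {
  target <- random_reference(4000, seed = 62)
  blocks <- partition_blocks(tibble::tibble(read_id = character(0),
                                            ref_start = integer(0)),
                             target, 2000L)
  ctg <- mk_contigs(c(a = substring(target, 1, 1500),
                      b = substring(target, 2001, 3000)))
  ctg$block <- c(0L, 1L)
  ev <- evaluate_blocks(ctg, blocks, target = target)
  expect_equal(nrow(ev$per_block), 2L)
  expect_equal(ev$summary$avg_n50, mean(c(1500L, 1000L)))
  expect_equal(ev$summary$avg_err, 0)
})
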
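test_that("block partition tiles the reference with a trailing partial block", {
  mapped <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                           ref_start = c(0L, 9999L, 24000L))
  b <- partition_blocks(mapped, 25000L, 10000L)
  expect_equal(nrow(b), 3L)
  expect_equal(b$start, c(0L, 10000L, 20000L))
  expect_equal(b$end, c(10000L, 20000L, 25000L))
  # half-open convention: ref_start 9999 belongs to block 0
  expect_setequal(b$read_ids[[1]], c("r1", "r2"))
  expect_equal(b$read_ids[[3]], "r3")
})

test_that("every mapped read lands in exactly one block", {
  set.seed(30)
  mapped <- tibble::tibble(read_id = sprintf("m%03d", 1:100),
                           ref_start = sample.int(24999L, 100) - 1L)
  b <- partition_blocks(mapped, 25000L, 10000L)
  all_ids <- unlist(b$read_ids)
  expect_equal(sort(all_ids), sort(mapped$read_id))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("left-over quality filter drops poor and N-rich reads", {
  rd <- make_reads(c(good = random_seq(80, seed = 31),
                     enn = paste(rep("N", 80), collapse = ""),
                     lowq = random_seq(80, seed = 32)))
  rd$qual <- list(rep(35L, 80), rep(35L, 80), rep(10L, 80))
  lo <- build_leftover_graph(rd, assembly_config())
  expect_equal(lo$reads$id, "good")
})

test_that("recruitment without bridging overlaps returns the local graph", {
  g1 <- random_seq(400, seed = 33)
  local <- tile_reads(g1, c(0L, 50L, 100L), prefix = "loc")
  lo_reads <- tile_reads(random_seq(400, seed = 34), c(0L, 50L), prefix = "lo")
  lo_reads$qual <- rep(list(rep(35L, 80)), 2)
  cfg <- assembly_config(kmer_size = 12, min_overlap = 25)
  leftover <- build_leftover_graph(lo_reads, cfg)
  lg <- build_overlap_graph(local, compute_overlaps(local, cfg, tag = "t"))
  merged <- recruit_and_merge(lg, leftover, cfg)
  expect_equal(sort(merged$vertices$id), sort(lg$vertices$id))
  expect_length(attr(merged, "recruited"), 0L)
})

test_that("bridging overlaps recruit the connected left-over component", {
  g <- random_seq(1000, seed = 35)
  # local reads cover [0, 400); left-over reads continue [350, 1000)
  local <- tile_reads(g, seq(0L, 320L, 40L), prefix = "loc")
  lo <- tile_reads(g, seq(350L, 900L, 45L), prefix = "lo")
  lo$qual <- rep(list(rep(35L, 80)), nrow(lo))
  cfg <- assembly_config(kmer_size = 12, min_overlap = 25)
  leftover <- build_leftover_graph(lo, cfg)
  lg <- build_overlap_graph(local, compute_overlaps(local, cfg, tag = "t"))
  merged <- recruit_and_merge(lg, leftover, cfg)
  expect_setequal(attr(merged, "recruited"), lo$id)
  # recruitment soundness: every recruited read connects to a local read
  comp <- igraph::components(igraph::graph_from_data_frame(
    merged$edges[, c("read_a", "read_b")], directed = FALSE,
    vertices = merged$vertices$id))$membership
  expect_equal(length(unique(comp)), 1L)
  # the left-over graph itself is untouched
  expect_equal(leftover$reads$id, lo$id)
})

test_that("the left-over graph is immutable across block assemblies", {
  ref <- random_reference(20000, seed = 36)
  mt <- mutate_target(ref, insertions = data.frame(count = 2, length = 400),
                      seed = 37)
  rd <- simulate_reads(mt$target, depth = 8, read_len = 80, seed = 38)
  sp <- split_by_insertions(rd, mt$truth, 80L)
  alg <- tibble::tibble(read_id = sp$mapped$id, ref_start = sp$mapped$ref_start)
  cfg <- assembly_config(block_len = 10000L)
  leftover <- build_leftover_graph(sp$leftover, cfg)
  snapshot <- leftover
  blocks <- partition_blocks(alg, ref, cfg$block_len)
  a1 <- assemble_block(blocks[1, ], rd, leftover, cfg)
  a2 <- assemble_block(blocks[2, ], rd, leftover, cfg)
  expect_identical(leftover$reads, snapshot$reads)
  expect_identical(leftover$edges, snapshot$edges)
  expect_identical(leftover$index$occ, snapshot$index$occ)
  # recruitment is order-independent
  b2 <- assemble_block(blocks[2, ], rd, leftover, cfg)
  expect_equal(sort(b2$recruited), sort(a2$recruited))
})

test_that("distance-dependent alignment constraints prune distant weak edges", {
  lens <- c(p = 80L, q = 80L)
  g <- fabricate_graph(lens, list(
    list(a = "p", b = "q", end_a = "R", end_b = "L", orient = "F", diag = 55L,
         mm = 2L)))
  tiers <- tibble::tibble(max_dist = c(1000, Inf),
                          min_len = c(20L, 40L), max_mm = c(2L, 1L))
  near <- tibble::tibble(read_id = c("p", "q"), ref_start = c(0L, 40L))
  far <- tibble::tibble(read_id = c("p", "q"), ref_start = c(0L, 30000L))
  expect_equal(nrow(distance_constrained_overlaps(g, near, tiers)$edges), 1L)
  expect_equal(nrow(distance_constrained_overlaps(g, far, tiers)$edges), 0L)
  # a constant-default constraint changes nothing
  const <- function(d) list(min_len = 20L, max_mm = 2L)
  expect_equal(nrow(distance_constrained_overlaps(g, far, const)$edges), 1L)
  expect_equal(distance_constrained_overlaps(g, far, NULL)$edges, g$edges)
})

test_that("empty blocks and empty left-over pools degrade gracefully", {
  ref <- random_reference(5000, seed = 39)
  blocks <- partition_blocks(tibble::tibble(read_id = character(0),
                                            ref_start = integer(0)),
                             ref, 5000L)
  asm <- assemble_block(blocks[1, ], make_reads(c(z = "ACGTACGTACGT")), NULL,
                        assembly_config())
  expect_equal(nrow(asm$contigs), 0L)
  lo <- build_leftover_graph(make_reads(character(0)), assembly_config())
  expect_equal(nrow(lo$reads), 0L)
})

test_that("one shared left-over pass serves many blocks; naive re-pooling pays per block", {
  ref <- random_reference(25000, seed = 40)
  mt <- mutate_target(ref, insertions = data.frame(count = 2, length = 300),
                      seed = 41)
  rd <- simulate_reads(mt$target, depth = 6, read_len = 80, seed = 42)
  sp <- split_by_insertions(rd, mt$truth, 80L)
  alg <- tibble::tibble(read_id = sp$mapped$id, ref_id = "ref",
                        ref_start = sp$mapped$ref_start,
                        strand = sp$mapped$strand, edit_distance = 0L)
  cfg <- assembly_config(block_len = 5000L)
  reset_overlap_pass_counts()
  res <- assemble_blocks(rd, alg, ref, cfg, recruit = TRUE)
  counts <- overlap_pass_counts()
  expect_equal(unname(counts["leftover"]), 1L)
  expect_equal(unname(counts["local"]), 5L)
  reset_overlap_pass_counts()
  res_naive <- assemble_blocks(rd, alg, ref, cfg, recruit = TRUE,
                               reuse_leftover = FALSE)
  expect_equal(unname(overlap_pass_counts()["leftover"]), 5L)
  reset_overlap_pass_counts()
})
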
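test_that("the illustrative triangle removes only the light edge", {
  lens <- c(v = 100L, w = 100L, z = 100L)
  edges <- list(
    list(a = "v", b = "w", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "w", b = "z", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "v", b = "z", end_a = "R", end_b = "L", orient = "F", diag = 80L))
  g <- fabricate_graph(lens, edges)
  red <- transitive_reduction(g)
  kept <- paste(red$edges$read_a, red$edges$read_b)
  expect_setequal(kept, c("v w", "w z"))
})

test_that("a triangle whose candidate is heaviest removes nothing", {
  lens <- c(v = 100L, w = 100L, z = 100L)
  # make (v,z) the longest alignment: weights 60, 60 vs 70
  edges <- list(
    list(a = "v", b = "w", end_a = "R", end_b = "L", orient = "F", diag = 40L,
         len = 60L),
    list(a = "w", b = "z", end_a = "R", end_b = "L", orient = "F", diag = 40L,
         len = 60L),
    list(a = "v", b = "z", end_a = "R", end_b = "L", orient = "F", diag = 80L,
         len = 70L))
  g <- fabricate_graph(lens, edges)
  red <- transitive_reduction(g)
  expect_equal(nrow(red$edges), 3L)
})

test_that("transitive reduction matches the exhaustive fixpoint oracle", {
  for (seed in 1:40) {
    g <- random_overlap_graph(seed)
    red <- transitive_reduction(g)
    ov_in <- g$edges[g$edges$kind == "overlap", ]
    want <- oracle_transitive(ov_in)
    got <- red$edges[red$edges$kind == "overlap", ]
    expect_setequal(got$edge_id, want$edge_id)
  }
})

test_that("transitive reduction is idempotent", {
  for (seed in c(5, 17, 29)) {
    g <- random_overlap_graph(seed)
    once <- transitive_reduction(g)
    twice <- transitive_reduction(once)
    expect_equal(twice$edges$edge_id, once$edges$edge_id)
  }
})

test_that("a branch-free chain condenses to one inner edge and no real edge", {
  g <- random_seq(300, seed = 14)
  reads <- tile_reads(g, c(0L, 50L, 100L), len = 80L)
  cfg <- assembly_config(kmer_size = 10, min_overlap = 25, max_mismatches = 0)
  graph <- build_overlap_graph(reads, compute_overlaps(reads, cfg, tag = "t"))
  pg <- build_path_graph(transitive_reduction(reduce_containments(graph)))
  expect_equal(nrow(pg$inner), 1L)
  expect_equal(nrow(pg$vertices), 2L)
  expect_equal(nrow(pg$real), 0L)
  expect_equal(length(pg$inner$reads[[1]]), 3L)
  expect_equal(pg$inner$length, 180L)
})

test_that("a shared read terminating several unique paths gets a real edge", {
  # a unique path b-x-d, then two alternative continuations from d's far end
  lens <- c(b = 80L, x = 80L, d = 80L, e = 80L, f = 80L)
  edges <- list(
    list(a = "b", b = "x", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "x", b = "d", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "d", b = "e", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "d", b = "f", end_a = "R", end_b = "L", orient = "F", diag = 41L))
  pg <- build_path_graph(fabricate_graph(lens, edges))
  expect_equal(nrow(pg$inner), 3L)
  main <- pg$inner[pg$inner$n_reads == 3L, ]
  expect_setequal(c(main$reads[[1]][1], main$reads[[1]][3]), c("b", "d"))
  expect_equal(pg$real$read, "d")
  expect_setequal(c(pg$real$v1, pg$real$v2), c("d|L", "d|R"))
})

test_that("a star hub yields short inner edges with real edges at the hub", {
  lens <- c(h = 80L, r1 = 80L, r2 = 80L, r3 = 80L)
  edges <- list(
    list(a = "h", b = "r1", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "h", b = "r2", end_a = "R", end_b = "L", orient = "F", diag = 45L),
    list(a = "h", b = "r3", end_a = "R", end_b = "L", orient = "F", diag = 50L))
  pg <- build_path_graph(fabricate_graph(lens, edges))
  expect_equal(nrow(pg$inner), 3L)
  expect_true(all(pg$inner$n_reads == 2L))
  expect_equal(pg$real$read, "h")
  want <- oracle_unique_paths(
    fabricate_graph(lens, edges)$edges, names(lens))
  got <- sort(vapply(pg$inner$reads, function(r) {
    alt <- rev(r)
    paste(if (paste(r, collapse = ",") <= paste(alt, collapse = ","))
      r else alt, collapse = ",")
  }, character(1)))
  expect_equal(got, want)
})

test_that("unique paths match the independent enumerator on random graphs", {
  for (seed in 41:70) {
    g <- random_overlap_graph(seed)
    red <- transitive_reduction(g)
    pg <- build_path_graph(red)
    act <- setdiff(red$vertices$id, red$exemplar_of$read)
    ov <- red$edges[red$edges$kind == "overlap" &
                      red$edges$read_a %in% act & red$edges$read_b %in% act, ]
    want <- oracle_unique_paths(ov, act)
    got <- sort(vapply(pg$inner$reads, function(r) {
      alt <- rev(r)
      paste(if (paste(r, collapse = ",") <= paste(alt, collapse = ","))
        r else alt, collapse = ",")
    }, character(1)))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("reads are conserved between overlap graph and path graph", {
  for (seed in c(3, 23, 57)) {
    g <- random_overlap_graph(seed)
    red <- transitive_reduction(g)
    pg <- build_path_graph(red)
    act <- setdiff(red$vertices$id, red$exemplar_of$read)
    in_paths <- unique(unlist(pg$inner$reads))
    expect_setequal(in_paths, act)
    # interior reads (not chain terminals) appear in exactly one inner edge
    occur <- table(unlist(pg$inner$reads))
    terminals <- unique(unlist(lapply(pg$inner$reads, function(r)
      c(r[1], r[length(r)]))))
    interior <- setdiff(names(occur), terminals)
    expect_true(all(occur[interior] == 1L))
  }
})

test_that("error-free tiled reads over a repeat-free sequence give one path", {
  g <- random_reference(3000, seed = 81)
  rd <- simulate_reads(g, depth = 12, read_len = 80, error_rate = 0, seed = 82)
  aln <- compute_overlaps(rd, assembly_config(), tag = "t")
  graph <- transitive_reduction(reduce_containments(build_overlap_graph(rd, aln)))
  pg <- build_path_graph(graph)
  expect_equal(nrow(pg$inner), 1L)
})
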
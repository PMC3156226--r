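# Minimal hand-built path graph: two chains joined through one shared read.
two_chain_pg <- function() {
  # chains [a, j], [j, b], [j, c] joined at the shared read j
  lens <- c(a = 80L, j = 80L, b = 80L, c = 80L)
  edges <- list(
    list(a = "a", b = "j", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "j", b = "b", end_a = "R", end_b = "L", orient = "F", diag = 40L),
    list(a = "j", b = "c", end_a = "R", end_b = "L", orient = "F", diag = 45L))
  g <- fabricate_graph(lens, edges)
  build_path_graph(g)
}

test_that("real-edge scores combine alignment identity and coverage", {
  pg <- two_chain_pg()
  expect_equal(nrow(pg$real), 1L)
  cfg <- assembly_config()
  sc <- score_real_edge(pg$real[1, ], pg, cfg)
  expect_equal(sc$quality_term, 1.0)   # mismatch-free alignments
  # identity of a path with 2 mismatches over 100 aligned columns is 0.98
  pg2 <- two_chain_pg()
  pg2$inner$identity <- 1 - 2 / 100
  sc2 <- score_real_edges(pg2, cfg)
  expect_equal(unique(sc2$quality_term), 0.98)
  # doubling coverage cannot lower the combined score
  pg3 <- pg2
  pg3$inner$coverage <- pg2$inner$coverage * 2
  sc3 <- score_real_edges(pg3, cfg)
  expect_gte(sc3$combined[1], sc2$combined[1])
})

test_that("a cycle-free path graph selects every real edge", {
  g <- random_reference(2000, seed = 31)
  rd <- simulate_reads(g, depth = 10, read_len = 80, error_rate = 0, seed = 32)
  aln <- compute_overlaps(rd, assembly_config(), tag = "t")
  gr <- transitive_reduction(reduce_containments(build_overlap_graph(rd, aln)))
  pg <- build_path_graph(gr)
  sg <- build_spanning_subgraph(pg, assembly_config())
  expect_equal(sort(sg$real_selected$real_id), sort(pg$real$real_id))
  expect_equal(nrow(sg$repeat_branches), 0L)
  expect_length(sg$marked_cycles, 0L)
  expect_false(reassembler:::has_directed_cycle(sg))
})

test_that("a heterozygous SNP cluster forms a marked similar bubble", {
  set.seed(41)
  g1 <- random_reference(1200, seed = 42)
  # second haplotype: 4 substitutions within a 16 bp window
  g2 <- g1
  for (i in c(600, 604, 609, 615)) {
    old <- substring(g2, i, i)
    substr(g2, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  rd1 <- simulate_reads(g1, depth = 6, read_len = 80, error_rate = 0, seed = 43)
  rd2 <- simulate_reads(g2, depth = 6, read_len = 80, error_rate = 0, seed = 44)
  rd2$id <- sub("^sim", "hap2", rd2$id)
  rd <- dplyr::bind_rows(rd1, rd2)
  asm <- assemble(rd)
  marked <- asm$subgraph$marked_cycles
  sim_marks <- Filter(function(m) m$type == "undirected_similar", marked)
  expect_gte(length(sim_marks), 1L)
  # the bubble collapses onto one haplotype: a single long contig remains
  expect_lte(sum(asm$contigs$length > 500), 1L)
})

test_that("cycle classification separates directed loops from bubbles", {
  # alternating inner/real edge ring = orientation-consistent repeat cycle
  cyc_dir <- tibble::tibble(
    eid = c("P1", "R1", "P2", "R2"), type = c("inner", "real", "inner", "real"),
    v1 = c("a|L", "b|L", "b|R", "c|R"), v2 = c("b|L", "b|R", "c|R", "a|L"),
    from = c("a|L", "b|L", "b|R", "c|R"), to = c("b|L", "b|R", "c|R", "a|L"))
  pgstub <- two_chain_pg()
  expect_equal(classify_cycle(cyc_dir, pgstub), "directed")
  # two inner edges meeting head-on at both junctions = undirected
  pg <- two_chain_pg()
  ids <- pg$inner$inner_id
  cyc_und <- tibble::tibble(
    eid = ids[1:2], type = "inner",
    v1 = pg$inner$v1[1:2], v2 = pg$inner$v2[1:2],
    from = c(pg$inner$v1[1], pg$inner$v2[2]),
    to = c(pg$inner$v2[1], pg$inner$v1[2]))
  expect_match(classify_cycle(cyc_und, pg), "^undirected")
})

test_that("random branch sequences classify as dissimilar, near-identical as similar", {
  expect_lt(reassembler:::global_identity(random_seq(100, seed = 1),
                                          random_seq(100, seed = 2)), 0.6)
  s <- random_seq(100, seed = 3)
  s2 <- s
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"), substring(s, 50, 50))[1]
  expect_gte(reassembler:::global_identity(s, s2), 0.99)
})

test_that("a two-copy repeat triggers a directed cycle cut with recorded branches", {
  gnm <- repeat_genome(6000L, rep_len = 300L, seed = 61, pos2 = 4001L)
  rd <- simulate_reads(gnm, depth = 15, read_len = 80, error_rate = 0, seed = 62)
  asm <- assemble(rd, use_mates = FALSE)
  expect_gte(nrow(asm$contigs), 2L)
  expect_gte(nrow(asm$subgraph$repeat_branches), 2L)
  expect_false(reassembler:::has_directed_cycle(asm$subgraph))
  # flank contigs are exact genome sequence; the collapsed repeat contig may
  # carry flank context from either copy in its low-coverage edge columns
  vc <- valid_contigs(asm$contigs, gnm, max_mm_frac = 0.01)
  expect_true(all(vc$valid[vc$length >= 150]))
})

test_that("mate pairs re-link cut repeat branches and reduce contig count", {
  gnm <- repeat_genome(6000L, rep_len = 300L, seed = 61, pos2 = 4001L)
  rd <- simulate_reads(gnm, depth = 15, read_len = 80, error_rate = 0,
                       paired = TRUE, insert_mu = 500, insert_sd = 30,
                       seed = 63)
  asm_cut <- assemble(rd, use_mates = FALSE)
  asm_res <- assemble(rd, use_mates = TRUE)
  expect_lt(nrow(asm_res$contigs), nrow(asm_cut$contigs))
  big <- asm_res$contigs$seq[which.max(asm_res$contigs$length)]
  expect_gte(nchar(big), 5500L)
  expect_true(contig_matches_genome(big, gnm))
  # duplicated repeat paths share read provenance
  dup <- asm_res$subgraph$inner[!is.na(asm_res$subgraph$inner$dup_of), ]
  expect_gte(nrow(dup), 1L)
  orig <- asm_res$subgraph$inner[asm_res$subgraph$inner$inner_id %in% dup$dup_of, ]
  expect_equal(sort(unique(unlist(dup$reads))), sort(unique(unlist(orig$reads))))
})

test_that("no mate pairs leaves the cut subgraph unchanged", {
  gnm <- repeat_genome(6000L, rep_len = 300L, seed = 61, pos2 = 4001L)
  rd <- simulate_reads(gnm, depth = 15, read_len = 80, error_rate = 0, seed = 62)
  asm <- assemble(rd, use_mates = FALSE)
  sg2 <- resolve_repeats_with_mates(asm$subgraph, rd)
  expect_equal(nrow(sg2$real_selected), nrow(asm$subgraph$real_selected))
  expect_equal(sum(sg2$inner$active), sum(asm$subgraph$inner$active))
})

test_that("fragmentary cycle detection needs branches, short paths and coverage", {
  mk_sg <- function(cov_link = 30, with_tips = TRUE) {
    inner <- tibble::tibble(
      inner_id = c("L1", "LNK", "R1", "T1", "T2", "X1", "X2"),
      v1 = c("u0|L", "u|R", "v|R", "u|R", "v|R", "u|R", "v|R"),
      v2 = c("u|R", "v|R", "w0|R", "t1|L", "t2|L", "x1|L", "x2|L"),
      reads = list("u0", c("u", "v"), "w0", "t1", "t2", "x1", "x2"),
      orients = rep(list("F"), 7),
      offsets = rep(list(0L), 7),
      length = c(500L, 400L, 500L,
                 if (with_tips) c(90L, 90L) else c(900L, 900L), 500L, 500L),
      identity = 1, coverage = c(10, cov_link, 10, 10, 10, 10, 10),
      n_reads = 1L, active = TRUE, dup_of = NA_character_)
    structure(list(
      pg = NULL, inner = inner,
      real_selected = tibble::tibble(
        real_id = c("Ru", "Rv"), v1 = c("u|L", "v|L"), v2 = c("u|R", "v|R"),
        read = c("u", "v"), score = c(1, 1)),
      marked_cycles = list(),
      repeat_branches = tibble::tibble(cycle_id = integer(0),
                                       vertex = character(0),
                                       read = character(0)),
      cut_cycles = list(), config = assembly_config(),
      read_lens = c(u0 = 80L, u = 80L, v = 80L, w0 = 80L, t1 = 80L, t2 = 80L,
                    x1 = 80L, x2 = 80L),
      dangling_threshold = 160), class = "spanning_subgraph")
  }
  hit <- detect_fragmentary_cycles(mk_sg())
  expect_equal(nrow(hit$repeat_branches), 2L)
  expect_equal(nrow(hit$real_selected), 0L)
  # long adjacent paths: not fragmentary
  expect_equal(nrow(detect_fragmentary_cycles(mk_sg(with_tips = FALSE))$repeat_branches), 0L)
  # normal coverage on the linking path: not fragmentary
  expect_equal(nrow(detect_fragmentary_cycles(mk_sg(cov_link = 10))$repeat_branches), 0L)
})

test_that("greedy layout is invariant to the input ordering of reads", {
  g <- random_reference(3000, seed = 71)
  rd <- simulate_reads(g, depth = 8, read_len = 80, error_rate = 0.01, seed = 72)
  asm1 <- assemble(rd)
  set.seed(73)
  asm2 <- assemble(rd[sample(nrow(rd)), ])
  canon <- function(a) sort(pmin(a$contigs$seq, rc(a$contigs$seq)))
  expect_equal(canon(asm1), canon(asm2))
})

test_that("dangling threshold is strict: a tip at the threshold is kept", {
  edges <- tibble::tibble(eid = c("A", "B"), type = "inner",
                          v1 = c("p|L", "q|L"), v2 = c("q|R", "t|L"))
  len_by <- c(A = 500L, B = 160L)
  hang <- reassembler:::hanging_component(edges[2, ], "q|L",
                                          c("p|L", "q|R", "q|L"), len_by)
  expect_equal(hang$length, 160L)
  # cut_directed_cycle clips only when strictly below the threshold
  expect_false(hang$length < 160)
})
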
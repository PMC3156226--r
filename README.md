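# reassembler

An overlap-layout-consensus (OLC) assembler for short reads at **low
sequencing depth** (5–10×), written for resequencing studies that need to
see what read mapping cannot: novel insertions and highly diverged regions.
It is aimed at people running homology-guided (reference-assisted)
assemblies — reads are mapped to a related reference, partitioned into
blocks, and each block is reassembled locally, optionally extended by the
pool of reads that failed to map ("left-over" reads).

## The method in brief

De Bruijn assemblers need exact k-mer matches and 20–30× depth; at 7.5× a
single error can erase the only join between two reads. `reassembler`
instead computes **mismatch-tolerant gap-free overlap alignments**: read
pairs sharing a canonical k-mer are verified at the shared diagonal and kept
when the dovetail spans ≥ *min_overlap* bases with ≤ *max_mismatches*
mismatches. The classical OLC stack follows:

1. **Overlap graph** — vertices are reads; edges are overlap or containment
   alignments, weight = alignment length, score = alignment score. For each
   set of mutually contained reads an *exemplar* (longest, best-scoring) is
   kept; transitive edges (implied by two heavier edges `w(v,z) ≤ w(v,w),
   w(w,z)` through an intermediate read, orientation-consistent) are removed.
2. **Path graph** — maximal unique (branch-free) paths become *inner edges*;
   a read terminating ≥ 2 unique paths gets a *real edge* between its two
   ends.
3. **Layout** — real edges are selected greedily by a score mixing alignment
   identity and read coverage, `λ·quality + (1−λ)·min(cov/cov₀, 1)`.
   Directed cycles (repeats) are rejected and cut open at branch vertices;
   undirected cycles (bubbles) are kept and collapsed when their branch
   sequences are ≥ 90% identical, rejected otherwise. Mate pairs with known
   insert size re-link cut repeat branches by duplicating the repeat path.
4. **Consensus** — from each leaf the longest orientation-consistent path is
   extracted, paths sharing a subpath are deduplicated, and each column takes
   the majority base over all reads, contained reads included.

Per-block evaluation uses the positional **block N50** (largest `L` such
that valid contigs of length ≥ `L` cover ≥ 50% of block positions, a contig
being valid at ≤ 10% mismatches), the **error rate**
(valid-contig mismatches + invalid-contig length, over total contig
length), reference **dissimilarity** (contigs ≥ 75% similar,
length-weighted), and strict error-free **insertion recovery**. A bundled
simulator (mutated target genomes with recorded truth, depth-controlled
error-bearing reads, paired-end mode) makes the whole pipeline testable
without any external data.

## Worked example

```r
library(reassembler)

ref   <- random_reference(10000, seed = 1)
reads <- simulate_reads(ref, depth = 7.5, read_len = 80,
                        error_rate = 0.01, seed = 2)       # 938 reads
asm   <- assemble(reads, assembly_config(kmer_size = 12, min_overlap = 20))
glance(asm)
#> # A tibble: 1 × 6
#>   n_contigs total_bp longest   n50 n_repeat_branches n_marked_cycles
#> 1         9    10772    6149  6149                 0             106

ctg <- valid_contigs(asm$contigs, ref)
error_rate(ctg)        #> 0.0029
block_n50(ctg, ref)    #> 6149
```

At 7.5× with 1% substitution errors, two contigs of 6.1 kb and 3.9 kb carry
the backbone (the remaining entries are short spurs from error-heavy
reads); the per-column majority vote pushes the assembly error rate to
0.29%, well below the 1% raw read error. `n_marked_cycles` counts the
error/SNP bubbles that were detected and collapsed during layout.

The homology-guided mode runs per block against a shared left-over graph:

```r
blocks <- assemble_blocks(reads, alignments, reference,
                          assembly_config(block_len = 25000))
insertion_recovery(blocks$contigs, truth)
```

and a thin CLI covers the same workflows from a shell
(`exec/reassemble simulate|assemble|assemble-blocks|evaluate`).

## Package tour

| area | functions |
|---|---|
| I/O | `load_reads`, `load_alignments`, `write_contigs`, `dump_graph`/`read_gfa` |
| overlaps | `index_kmers`, `candidate_pairs`, `align_overlap`, `compute_overlaps` |
| graph | `build_overlap_graph`, `reduce_containments`, `transitive_reduction`, `build_path_graph` |
| layout | `score_real_edge`, `build_spanning_subgraph`, `classify_cycle`, `cut_directed_cycle`, `detect_fragmentary_cycles`, `resolve_repeats_with_mates` |
| consensus | `extract_longest_paths`, `deduplicate_paths`, `call_consensus`, `assemble` |
| homology-guided | `partition_blocks`, `build_leftover_graph`, `recruit_and_merge`, `distance_constrained_overlaps`, `assemble_block`, `assemble_blocks` |
| simulation | `random_reference`, `mutate_target`, `simulate_reads`, `split_by_insertions` |
| evaluation | `valid_contigs`, `block_n50`, `error_rate`, `dissimilarity`, `insertion_recovery`, `evaluate_blocks` |

Results are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` graphics. The methods vignette
(`vignettes/low-coverage-assembly.Rmd`) documents the model, its parameters
and the design decisions in detail.
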
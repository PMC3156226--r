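---
title: "Low-coverage overlap-layout-consensus assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-coverage overlap-layout-consensus assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reassembler)
library(dplyr)
```

## Why an overlap-layout-consensus assembler for low depth

Resequencing projects keep costs down by sequencing many individuals at low
depth (5--10x). At that depth, de Bruijn assemblers struggle: they rely on
exact k-mer matches, and at 7.5x a single sequencing error can erase the only
evidence joining two reads. `reassembler` instead computes *mismatch-tolerant
overlap alignments* between reads, so a pair of 80 bp reads overlapping by 30
bases still joins even if the overlap carries one or two errors. The package
implements the full overlap-layout-consensus (OLC) stack plus a
homology-guided mode that assembles reads block by block along a related
reference genome and recruits unaligned ("left-over") reads where the sample
diverges from the reference -- the situation in which novel insertions live.

## The pipeline

### Overlap detection

Candidate read pairs are pairs sharing an identical k-mer (default `k = 13`),
found through a canonical k-mer index: each k-mer and its reverse complement
map to one key, so both relative orientations of every pair are examined.
K-mers containing `N` never seed candidates. Each candidate (pair,
orientation, diagonal) is verified by a *gap-free* alignment at that
diagonal: substitution errors dominate short-read data, and a gap-free model
keeps every read-to-layout offset exact, which the layout and consensus
stages exploit. An alignment qualifies if it is a suffix--prefix overlap of
at least `min_overlap` bases (default 25) or spans one read entirely
(a *containment*), with at most `max_mismatches` mismatches (default 2).
Scoring is match `+1`, mismatch `-2`; per pair and orientation only the best
alignment is kept.

`align_overlap()` exposes the same model as a standalone operation that scans
*every* diagonal, which the test suite compares against a brute-force oracle.

### Overlap graph, exemplars, transitive reduction

Vertices are reads; edges are overlap or containment alignments with weight
= alignment length and score = alignment score. Within each connected
component of containment edges an *exemplar* is chosen -- the longest read,
ties broken by the highest summed containment score, then id -- and all
overlap edges of the other (contained) reads are removed. Contained reads
are not discarded: their placement relative to the exemplar is recorded and
they vote again at consensus time.

An overlap edge is *transitive* when two orientation-consistent edges
through an intermediate read explain it with at least its weight. All
transitive edges are marked against the original edge set and deleted
together, which makes the result independent of edge order; equal-weight
triangles drop the (weakly) lightest edge. The suite checks this against an
exhaustive fixpoint oracle on hundreds of random overlap graphs.

### Path graph

Maximal *unique paths* -- chains extendable through reads whose two ends
each carry exactly one overlap edge -- are condensed into *inner edges*. The
two vertices of an inner edge are the outer ends of its first and last read,
as shared `(read, end)` nodes. A read that terminates two or more unique
paths receives a *real edge* joining its two end vertices: crossing it means
passing through the read from one of its ends to the other. Pure cycles of
pass-through reads (perfectly collapsed circular structure) are broken
deterministically at their lexicographically smallest read.

### Layout: greedy spanning subgraph and cycles

Real edges enter a priority queue ordered by a score combining the mean
alignment identity of the unique paths meeting at the edge (quality term)
and their mean read coverage, normalised at a target coverage:

`combined = lambda * quality + (1 - lambda) * min(coverage / coverage_target, 1)`

with `lambda = 0.5` and `coverage_target` defaulting to twice the median
per-path coverage. Candidates are selected greedily; a candidate whose
addition would close a cycle is classified first:

* **directed cycle** -- inner and real edges strictly alternate around the
  cycle, i.e. it can be traversed consistently with read orientation. This
  is the signature of a repeat. The candidate is rejected, short dangling
  paths (total length below `dangling_factor x mean read length`, strictly;
  default factor 2) hanging off the cycle are clipped, the cycle's real
  edges at every remaining branch vertex are cut, and the cut vertices are
  recorded as *repeat branches*.
* **undirected cycle** -- the traversal reverses direction where two inner
  edges meet head-on. The two arcs between the reversal vertices are laid
  out and their consensus sequences compared by global alignment (the second
  arc is seen reverse-complemented, so both strands are tried). Identity at
  or above `bubble_similarity` (default 0.90) means a sequencing-error or
  SNP bubble: the cycle is marked and collapsed onto its better-supported
  arc (more reads, then longer), dropping the weaker arc *as a whole* so the
  surviving branch stays traversable end to end. Below the threshold the
  structure is treated as a false alignment and the candidate is simply not
  selected; prior selections stand.

Bubbles that exist before any real edge is placed -- parallel unique paths
between the same two vertices -- are classified and resolved the same way
during initialisation.

Repeats whose cycle never closed (an overlap lost to errors) are found by
scanning for *fragmentary cycles*: a linking path between two branch
vertices, each adjacent to at least one short dangling path. On top of that
printed rule the linking path must show elevated coverage (at least 1.5x the
median per-path coverage). A collapsed two-copy repeat carries twice the
read density, while error tangles in repeat-free data do not; without the
coverage condition the rule fires throughout noisy low-coverage graphs and
fragments the assembly. Detected fragments are cut and recorded exactly like
directed cycles.

### Mate-pair repeat resolution

When reads carry mate links with an insert-size expectation, cut repeats
with exactly two branches can be re-linked. Entry paths at one branch and
exit paths at the other are paired by counting mate pairs whose implied span
(distance to the junction read through the entry path + repeat length +
distance through the exit path) lies within `insert_sd_tolerance` standard
deviations (default 3, plus one read length of slack for layout
granularity). Each unambiguous entry--exit assignment duplicates the repeat
path -- fresh private junction vertices, same reads, provenance shared
explicitly -- and re-links one copy; conflicting equal-support assignments
leave the branch cut with a warning. Ambiguity therefore costs contig length
but never produces a misassembly by construction.

### Path extraction and consensus

From every leaf of the spanning subgraph the longest orientation-consistent
(alternating) walk is computed, with inner edges contributing their
consensus-length estimate; the longest walks are then recomputed once from
the end vertices of those walks (`longest_path_fixpoint = TRUE` iterates to
a fixpoint instead). Walks sharing an inner edge are redundant: only the
longest of each sharing group is kept, so the final walks are pairwise
disjoint in inner edges. Length is measured in consensus base pairs, not
read count, matching how contig sizes are reported downstream.

Each final walk is laid out by composing the exact overlap offsets through
the shared junction reads; contained reads are placed through their
exemplar. Every column takes the majority base; ties break by higher summed
Phred quality, then alphabetically with `N` last. Columns with zero coverage
cannot occur in an overlap-driven layout and are asserted against rather
than padded.

## Homology-guided mode

`partition_blocks()` tiles the reference into fixed-length windows (0-based,
half-open; the trailing partial window is a block) and assigns each mapped
read to the block containing its alignment start. `build_leftover_graph()`
quality-filters the unaligned reads (mean Phred >= 20, at most one `N`) and
computes their overlap graph and k-mer index *once*. Per block,
`assemble_block()` overlaps the local reads, optionally applies
distance-dependent alignment constraint tiers (stricter `min_overlap` /
`max_mismatches` for read pairs far apart on the reference), computes
bridging alignments local-vs-left-over against the persistent index, and
recruits the connected component of every bridged left-over read (capped by
`max_recruit_reads`; `recruit_radius` restricts the closure to a hop radius
instead). The merged graph then runs through the ordinary pipeline. The
left-over graph is never mutated, so any number of blocks can share it --
the package counts overlap-computation passes (`overlap_pass_counts()`) to
make this observable: five blocks cost one left-over pass, versus five for
naive re-pooling.

Recruitment closure defaults to the full connected component because
insertions of several kb must be recruited in their entirety from a single
flank bridge; the cap bounds pathological components.

## The simulator and what it does (not) emulate

`random_reference()` draws i.i.d. bases at a chosen GC. `mutate_target()`
plants SNPs, 1--5 bp micro-indels and novel insertions (>= 100 bp, random
sequence) at uniform non-overlapping positions and records every event plus
a reference/target coordinate map, so evaluation needs no external truth.
`simulate_reads()` places `round(depth * G / read_len)` reads uniformly
(paired mode draws Gaussian insert sizes and emits innie pairs), applies
position-uniform substitution errors, assigns random strands, and encodes
the origin in the read id (`sim:<origin>:<strand>:<pair>:<serial>`).

The simulator reproduces the features this assembler is sensitive to --
depth, read length, substitution errors, insert-size spread, strandedness,
repeat structure via the reference supplied to it. It does not emulate
instrument-specific quality profiles, indel sequencing errors (a
substitution-only model is the default to match the gap-free overlap
model; alignment would have to be gapped otherwise), coverage biases, PCR
duplicates, or adapter artefacts. Passing tests on simulated data therefore
demonstrates the algorithmic behaviour, not performance on any particular
instrument's error profile.

## Evaluation metrics

A contig is *valid* for a block when its best free-end-gap placement on the
block's true sequence has at most 10% mismatches (both strands tried;
mismatch fraction over contig columns, so overhang counts against the
contig). Placement anchors exact 24-mers of the contig and evaluates whole
diagonals -- exact because contigs from substitution-error reads are
gap-free against the truth -- with a banded alignment fallback for small
anchor-free cases. The *block N50* is the largest contig length `L` such
that positions covered by valid contigs of length >= `L` total at least half
of the block, each position counted once. The *error rate* is (mismatches of
valid contigs + total length of invalid contigs) / total contig length. The
*dissimilarity* to a reference (used when no truth target exists) excludes
contigs below 75% similarity -- insertion-derived contigs have no reference
counterpart -- and length-weights the rest. An insertion counts as
*recovered* only when a contig contains the full inserted sequence with zero
mismatches, on either strand. Averages over blocks (`avgN50`, `avgERR`,
`avgDISS`) are unweighted means.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `kmer_size` | 13 | bases | candidate seeding; smaller finds overlaps whose exact match was shortened by errors |
| `min_overlap` | 25 | bases | floor on dovetail length; governs which coverage gaps break contigs |
| `max_mismatches` | 2 | count | error tolerance per overlap |
| `lambda_score` | 0.5 | -- | quality vs coverage weight in real-edge scores |
| `dangling_factor` | 2 | read lengths | tip-clipping threshold when cycles are cut |
| `bubble_similarity` | 0.90 | identity | error/SNP bubble vs false alignment |
| `insert_sd_tolerance` | 3 | SDs | mate concordance window for repeat resolution |
| `block_len` | 25000 | bases | homology-guided block size |

For 80 bp reads at depth around 7.5x a *low-coverage setting* of
`kmer_size = 12, min_overlap = 20` is recommended: with Poisson read starts
the probability that no qualifying overlap spans a junction scales as
`exp(-depth/read_len * (read_len - min_overlap))`, so lowering the floor
from 25 to 20 cuts expected contig breaks by roughly 40% at this depth,
while spurious 20 bp near-exact matches remain vanishingly unlikely at
block scale. The defaults stay at 13/25/2, which suit depths of 10x and up.

## Numerical and degenerate-input choices

* Ties everywhere break deterministically (score, then length, then
  lexicographic id); re-running on a shuffled read table yields the same
  contigs, which the suite asserts.
* Equal-weight transitive triangles remove the candidate edge (the rule is
  `<=`).
* `N` bases never seed k-mers and mismatch every base but `N` in
  verification; at consensus they are out-voted and win a column only when
  nothing else covers it.
* Empty inputs (no reads, empty blocks, empty left-over pools) return empty
  results rather than errors.
* Both orientations are assembled by default; `single_strand = TRUE` is
  available for pre-oriented reads.
* The collapsed repeat contig of a cut (unresolved) repeat can carry flank
  context of either copy in its first/last few columns, where only boundary
  reads of one copy vote; the copies are indistinguishable there without
  mate information.

## Problem sizes used by the tests

The bundled checks run entirely on simulated data at desk scale: 10 kb
sequences at depths 7.5--15x (about 950--1900 reads) for the de novo
properties, a 50 kb reference with ten 200--2000 bp insertions at 10x for
the homology-guided properties, and hundreds of random 12-read graphs for
the oracle comparisons. These sizes exercise every code path -- repeats,
bubbles, cuts, recruitment -- while each pipeline run stays in the
seconds-to-a-minute range in plain R.

## Known limitations

* Overlaps are gap-free; indel sequencing errors or indel polymorphisms
  within a read break overlaps instead of gapping them.
* Scaffolding across contigs and mapper integration are out of scope: the
  homology-guided mode consumes alignments (SAM or TSV) produced elsewhere.
* Repeat duplication handles the unambiguous two-branch case; nested or
  higher-multiplicity repeats stay cut (shorter contigs, no misassembly).
* The pure-R implementation targets block-scale local assemblies (tens of
  kb, thousands of reads per block), not whole-genome single runs.
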
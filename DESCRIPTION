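Package: reassembler
Title: Low-Coverage Overlap-Layout-Consensus Assembly with Homology-Guided
    Read Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An overlap-layout-consensus assembler for short-read data at low
    sequencing depth (5-10x). Detects mismatch-tolerant suffix-prefix overlaps
    between reads by shared-kmer seeding, builds an overlap graph with
    containment (exemplar) and transitive reduction, condenses unique paths
    into a path graph, resolves sequencing-error bubbles and repeat-induced
    directed cycles during a greedy spanning-subgraph layout (optionally using
    mate-pair inserts to duplicate repeats), and calls majority-vote consensus
    contigs. A homology-guided mode partitions reads mapped to a reference
    into blocks, assembles each block locally, and recruits unaligned
    ("left-over") reads from a single reusable left-over overlap graph so
    that novel insertions between homologous regions can be reconstructed.
    Includes a read simulator with recorded mutation truth and the matching
    evaluation metrics (block N50, error rate, dissimilarity, insertion
    recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
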
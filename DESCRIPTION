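Package: allodate
Title: Dating Whole-Genome Duplications and Allopolyploidy from Sequence
    Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for reconstructing the timing of
    whole-genome duplications and allopolyploid formation from genome
    sequence. Computes fourfold-degenerate transversion (4DTv) distances
    and Kimura two-parameter distances on aligned coding-sequence pairs,
    selects the pairs that enter the divergence distribution by protein
    anchor scoring, C-score filtering and dynamic-programming collinearity
    chaining, detects peaks in distance distributions and converts them to
    divergence times under a molecular clock, estimates LTR retrotransposon
    insertion ages from 5'/3' LTR divergence, partitions an allopolyploid's
    chromosomes into subgenomes by homology identity to a diploid
    reference, and summarises assemblies (N50/N90, GC, gaps, gene
    densities). A sequence-evolution simulator with planted divergence
    times, planted collinear blocks and planted subgenome labels makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    GenomicRanges,
    rtracklayer,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
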
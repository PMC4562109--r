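Package: ampliclone
Title: Detection and Exact Quantification of Clone Haplotypes in Mixed
    Amplicon Deep-Sequencing Samples
Version: 0.1.0
Authors@R:
    person("ampliclone", "developers", email = "ampliclone@example.org",
           role = c("aut", "cre"))
Description: Detects combinations of variants (haplotypes, "clones") carried
    together on sequencing fragments in one mixed ultra-deep amplicon
    sequencing sample and quantifies each clone's abundance exactly, counting
    every fragment once. Reads SAM alignments (unpadded and padded dialects,
    single or paired-end) against a FASTA reference, extracts per-read
    variants from the alignment operations, merges mate pairs with
    overlap-conflict masking, tabulates exact haplotype counts and
    coverage-adjusted percentages, and estimates the wild-type fraction as
    the complement. For overlapping multi-amplicon designs, haplotypes
    scattered across amplicons are reconnected by an iterative
    maximum-clique procedure on the variant co-occurrence graph. Includes a
    seeded mixed-clone read simulator that emits pre-aligned SAM with ground
    truth, so every stage is testable without external data, and CSV
    reporting with coding-sequence and amino-acid annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
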
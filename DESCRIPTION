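Package: hoxcomp
Title: Comparative Analysis of Hox Cluster Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics of vertebrate Hox gene clusters: detection of
    conserved noncoding elements (CNEs) by windowed percent-identity scanning of
    pairwise global alignments, classification of CNEs into phylogenetic depth
    groups (gnathostome, osteichthyan, sarcopterygian, tetrapod), library-free
    discovery of direct and inverted repeats by seed-and-extend self comparison,
    repeat-density statistics over masked regions, Tajima relative rate tests for
    nucleotide and protein alignments with Hasse-diagram synthesis of lineage
    rate orderings, and terminal branch-length fold comparisons. Includes a
    Jukes-Cantor simulator that generates multi-species cluster sequences with
    known planted CNEs, repeats and exons so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
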
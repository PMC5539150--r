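Package: luxcassette
Title: Mining, Topology and Phylogenetics of LuxI/LuxR Quorum-Sensing Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying LuxI (autoinducer synthase) and LuxR
    (acyl-homoserine-lactone responsive regulator) homologs in bacterial
    genomes: domain-based candidate mining from InterPro/CDD-style
    annotation tables, greedy identity-threshold redundancy reduction,
    pairing of luxI/luxR loci into canonical cassettes with gene-topology
    classification, amino-acid composition fold-change comparison between
    groups, reference-anchored alignment conservation scoring, and
    phylogenetic inference of horizontal gene transfer and cassette
    co-transfer from tree incongruence. Includes seeded synthetic-data
    generators with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    methods,
    ape,
    phangorn,
    phytools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
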
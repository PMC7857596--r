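Package: MesFinder
Title: Discovery and Classification of Folate-Independent Core Methionine
    Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics toolkit for discovering and classifying
    the four families of folate-independent ("core") methionine synthases
    (MesA, MesB, MesC, MesD) and related systems (split MetE, MesX/DUF1852,
    MetH, MetF, Wood-Ljungdahl markers) across prokaryotic proteomes.
    Provides local protein alignment with bit-score thresholds for family
    assignment, position-specific scoring profiles for domain detection,
    progressive multiple alignment with block trimming, catalytic-residue
    mapping and zinc-site compatibility classification, sequence-logo
    information content, genome-level repertoire and co-occurrence analysis,
    operon-adjacency detection, neighbor-joining phylogenies, and gene
    fitness estimation from randomly barcoded transposon (BarSeq) counts.
    Includes a seeded synthetic-data generator that emulates the structure
    of large reference-proteome screens in miniature, so every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
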
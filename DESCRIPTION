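Package: tcmariner
Title: Characterization of Tc1/mariner Transposons and Their Insertion Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for characterizing Tc1/mariner
    DNA transposons and their genomic insertion landscapes. Provides
    structural annotation of elements (terminal inverted repeat and
    target-site-duplication detection, ORF finding, DDE/D catalytic-triad
    family classification, full-length copy clustering), insertion-age
    profiling by Kimura two-parameter divergence, calling of insertion
    sites from transposon-genome junction reads with a seed-and-extend
    unique-best mapper, TA target-site sequence profiling (position
    frequency matrices, information content, palindrome symmetry),
    enrichment of insertion sites across genomic feature tracks against a
    random-locus null, germline-mobilization statistics (litter
    frequencies, re-transposition and enhancer-trap rates, local hopping,
    excision footprints), and a synthetic-data module that generates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
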
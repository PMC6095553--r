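Package: mitomosaic
Title: Comparative Structural Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the comparative structural analysis of circular plant
    mitochondrial genomes: seed-and-extend repeat detection with direct or
    inverted orientation and size-tier classification, double-cut-and-join
    (DCJ) gene-order rearrangement distances, scanning of orthologous intron
    alignments for deletions flanked by short direct repeats, pseudogene
    fragment detection in intergenic spacers, shared and anonymous sequence
    accounting between genome pairs, Nei-Gojobori synonymous and
    nonsynonymous substitution estimation with conversion to absolute rates
    per billion years, and classification of long reads spanning repeat
    pairs as parental or recombined. Includes a seeded generator of
    synthetic circular mitogenomes with planted repeats, pseudogene
    fragments, intron deletions, rearrangements and simulated long reads,
    with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
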
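Package: rnachord
Title: Circular Chord Diagrams of RNA Secondary Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Folds short RNA (or DNA) sequences into a minimum-free-energy
    secondary structure and a Boltzmann-ensemble base-pair probability
    matrix, and draws both in a single circular chord diagram: an outer
    ring of colour-coded bases and an inner layer of arcs whose colour and
    thickness encode pair probability, with the MFE pairing overlaid in
    dark red. Includes a self-contained simplified thermodynamic folding
    engine validated against exhaustive enumeration, readers for RNAfold
    text and PostScript dot-plot output so an external folder can be used
    as a drop-in backend, Smith-Waterman local alignment with difference
    highlighting for pairwise comparison of two sequences, descriptive
    comparison statistics, and an end-to-end pipeline that turns a FASTA
    file into per-sequence plots, a two-panel comparative figure, reports
    and a reproducible ZIP bundle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stringr,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
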
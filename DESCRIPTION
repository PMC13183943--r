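Package: climkit
Title: Deep Mutational Scanning, Toeprinting and Steric Analysis of the CliM Arrest Peptide
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the quantitative analyses surrounding the CliM
    ribosome-arrest peptide: simulation and counting of NNK saturation
    mutagenesis (deep mutational scanning) libraries from paired-end reads,
    growth-rate and relative-fitness estimation under antibiotic selection,
    a linear codon-offset model for toeprint fragment lengths, Monte-Carlo
    van-der-Waals overlap volumes, in-silico sidechain truncation, backbone
    hydrogen-bond censuses, rigid superposition, and partial-least-squares
    functional-mode analysis of conformational ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    knitr
Config/testthat/edition: 3
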
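Package: ighfold
Title: Polymer Modeling and Spatial Statistics for Antigen Receptor Locus
    Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the three-dimensional architecture of the
    mouse immunoglobulin heavy-chain (Igh) locus and similar regions from
    Capture Hi-C and 3D DNA FISH data. Provides binning, iterative-correction
    balancing and observed-over-expected normalization of contact matrices; a
    coarse-grained beads-on-a-string Monte-Carlo polymer simulator with
    pairwise spherical-well potentials; inverse fitting of the well depths so
    that the simulated ensemble reproduces a target contact map
    (fit_polymer(), a classed model object with coef/predict/simulate
    methods); single-structure ensemble statistics (interaction partners,
    V-D contact geometry, center-of-mass profiles, conformational
    clustering); virtual-4C extraction and modified Z-score calling of
    interchromosomal contacts with replicate intersection; and downstream
    statistics for 3D FISH spot tables (closest-pair distances, random
    association probabilities, association tests). Seeded synthetic-data
    generators emulate each input so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
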
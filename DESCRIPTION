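Package: cdrscreen
Title: High-Content Screening Analysis of Circular Dorsal Ruffle Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based RNAi screens that score the
    formation of circular dorsal ruffles (CDRs) in fibroblasts. Covers
    segmentation of nuclei and cells from three-channel fluorescence images
    (supervised pixel classification of CDR pixels, seeded watershed cell
    segmentation, power-spectrum focus quality control), per-image scoring,
    per-plate normalization against negative-control siRNA wells, per-siRNA
    CDR scores and gene-level hit validation. Includes a ground-truth
    synthetic plate generator for end-to-end validation, and quantification
    helpers for chemotaxis track metrics, corrected total cell fluorescence
    and oscillatory protrusion dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
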
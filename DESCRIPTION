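Package: stripnet
Title: Multilevel Strip Pooling Networks for Variable-Size Ultrasound Plaque Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of carotid plaque echogenicity from grayscale
    ultrasound regions of interest of arbitrary size. Implements multilevel
    strip pooling (MSP) and spatial pyramid pooling (SPP) heads that turn
    variable-size convolutional feature maps into fixed-length vectors, a
    small VGG-style convolutional backbone trained by stochastic gradient
    descent with momentum, a seeded generator of speckle-noised strip-textured
    synthetic plaque images in three echogenicity classes, stratified k-fold
    cross-validation, and per-class sensitivity/specificity/precision/F1
    reporting from 3x3 confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    readr,
    png,
    tiff,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
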
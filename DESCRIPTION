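Package: cryopick
Title: Convolutional Neural Network Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Template-free recognition of single particles in noisy cryo-electron
    microscopy micrographs with an eight-layer convolutional neural network
    (three convolutional layers with sigmoid activation, three average-pooling
    layers, and a fully connected scoring head) trained from first principles by
    error back-propagation on a squared-error loss. Provides the full picking
    pipeline: rotation-augmented training on labelled particle/non-particle
    boxes, raster scanning of micrographs with four-fold rotation-averaged
    scoring, local-maximum and score-threshold candidate selection, a pixel
    standard-deviation filter against contaminated areas, precision-recall
    evaluation with F-beta threshold selection, a synthetic micrograph simulator
    with controlled signal-to-noise ratio and exact ground truth, and readers
    and writers for MRC micrographs and EMAN2-style box files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
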
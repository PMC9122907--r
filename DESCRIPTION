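Package: fazseg
Title: Lightweight Attention U-Nets for Foveal Avascular Zone Segmentation
    and Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains a family of lightweight encoder-decoder
    segmentation networks with bounded channel attention and a channel-narrowing
    bottleneck, targeted at en-face retinal angiography (OCTA) images.  Implements
    the full downstream analysis pipeline for the foveal avascular zone (FAZ):
    probability-map binarisation, contour extraction, largest-region selection and
    morphometry (area, perimeter, circularity index) in physical units, plus
    agreement statistics (Bland-Altman, Pearson) and single-covariate logistic ROC
    analysis.  A seeded synthetic OCTA-like image generator with analytic ground
    truth supports end-to-end testing without clinical data.  The convolutional
    engine (convolution, batch normalisation, channel attention, Adam, backprop)
    is implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    rlang,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff
Config/testthat/edition: 3
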
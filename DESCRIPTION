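Package: flimq
Title: Fluorescence Lifetime Estimation for SPAD-Array TCSPC Data with
    Quantized Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis stack for time-correlated single-photon
    counting (TCSPC) fluorescence lifetime estimation on single-photon
    avalanche diode (SPAD) arrays. Provides a synthetic decay and pixel-array
    frame simulator with Poisson and additive Gaussian noise, per-pixel
    instrument-response-function (IRF) calibration (peak alignment, hot-pixel
    masking, background subtraction), the center-of-mass lifetime estimator
    with truncation bias correction, nonlinear least-squares deconvolution
    fitting, a quantized one-dimensional convolutional neural network (QCNN)
    lifetime regressor trained with straight-through-estimator
    quantization-aware training, and an accuracy/precision evaluation harness
    in decibels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
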
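Package: scretinex
Title: Self-Calibrated Multi-Stage Retinex Enhancement for Low-Light Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised low-light image enhancement by Retinex
    illumination-reflectance decomposition. A tiny weight-shared
    convolutional network estimates a residual illumination map over a
    multi-stage cascade, a second self-calibration network drives all
    stages toward a common fixed point so that a single stage suffices at
    inference, and training minimises a four-term loss (fidelity,
    edge-aware smoothness in YUV, feature-space perceptual, and gradient
    sparsity) on unlabeled dark images. Includes a synthetic scene
    generator with known ground-truth reflectance and illumination,
    full-reference evaluation metrics, checkpointing, and a command-line
    interface. All network layers, gradients and the Adam optimiser are
    implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
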
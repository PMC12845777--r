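Package: gefay
Title: Group-Enhanced Fusion Attention for Lightweight Weed Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Group-Enhanced Fusion Attention (GEFA) operator
    and a single-stage anchor-based detector (GEFAY) built around it, together
    with a zoo of comparison attention modules (SE, ECA, CA, CBAM, MLCA)
    sharing one plug-in interface, an exact parameter and FLOP profiler with a
    calibration routine for the attention hyperparameters, a desk-scale
    training and evaluation harness (target assignment, composite detection
    loss, non-maximum suppression, mAP), and a deterministic synthetic
    weed-field image generator so the full stack runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
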
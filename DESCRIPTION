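Package: cecg
Title: Signal Quality and Sleep Position Classification for Capacitive ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully automatic processing framework for single-lead capacitive
    electrocardiogram (cECG) recordings measured through cloth while a subject
    lies on an instrumented bed. Provides a synthetic cECG generator with
    position-dependent morphology and controlled quality degradation, a
    preprocessing chain (zero-phase Butterworth band-pass filtering, overlapped
    fixed-length segmentation, per-segment z-scoring), a parameterized family of
    one-dimensional convolutional neural networks (3 to 8 convolutional blocks)
    trained by backpropagation with Adam, stratified k-fold cross-validation
    with class-wise precision and recall, and a hierarchical annotation pipeline
    in which a signal-quality classifier gates segments before a sleep-position
    classifier labels the clear ones.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
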
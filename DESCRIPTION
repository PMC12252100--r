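Package: kanbeat
Title: ECG Beat Classification with Multi-Scale Convolutions, Channel
    Attention, BiGRUs and Kolmogorov-Arnold Heads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for five-class (AAMI) electrocardiogram beat
    classification from single-lead recordings. Provides a seeded
    synthetic ECG beat generator, a preprocessing pipeline (R-peak
    windowing, periodized discrete-wavelet denoising, min-max
    normalization, train/validation/test splitting), two class-imbalance
    remedies (multi-class focal loss and from-scratch SMOTE
    oversampling restricted to training folds), a hybrid neural network
    built from first principles (multi-scale 1-D convolutions with
    learnable fusion weights, partial-convolution blocks with efficient
    channel attention, bidirectional GRUs, and a Kolmogorov-Arnold
    B-spline head), Adam training with hand-derived backpropagation,
    the full per-class and macro metric suite, ablation and
    imbalance-strategy comparisons, and minimal WFDB-format I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
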
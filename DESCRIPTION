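Package: eegannot
Title: CNN-Guided Annotation of Artifacts in Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for improving manual artifact annotation of multichannel
    resting-state EEG with a convolutional neural network. Provides minimal
    preprocessing (Hamming-window FIR bandpass with a transition-bandwidth
    filter-length rule, 10-20 channel selection, average reference),
    overlapping 1-s segmentation with interval-intersection labelling, Morlet
    wavelet time-frequency tensors, a grouped-convolution CNN with
    class-weighted cross-entropy and averaged SGD trained under subject-wise
    cross-validation, per-sample probability traces, and a revision loop that
    selects confidently misclassified segments for dual-rater re-annotation,
    merges the decisions into a revised gold standard (with Cohen's kappa
    agreement), and retrains. Includes a synthetic EEG generator with
    ground-truth artifact intervals and simulated raters so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
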
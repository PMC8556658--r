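Package: sleepgcn
Title: Multi-View Spatial-Temporal Graph Convolutional Sleep Staging with
    Domain Generalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies 30-second polysomnography epochs into the five AASM
    sleep stages (Wake, N1, N2, N3, REM) with a two-view spatial-temporal
    graph convolutional network. One brain view is a functional-connectivity
    graph learned adaptively from per-epoch differential-entropy features;
    the other is a fixed graph built from physical electrode distances.
    Each view passes through spatial and temporal attention, Chebyshev
    spectral graph convolution and temporal convolution before fusion.
    An adversarial domain-generalization head with a gradient reversal
    layer extracts subject-invariant features so that models transfer to
    unseen subjects without fine-tuning. Includes differential-entropy
    feature extraction, fixed-adjacency baselines (full, KNN, Pearson,
    phase-locking value, mutual information), subject-independent
    cross-validation with accuracy, macro-F1 and Cohen's kappa, attention
    and adjacency exports, and a synthetic multi-subject cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
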
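Package: ogt
Title: Ordinal Ground Truth from Continuous Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns multiple noisy real-time continuous annotations of a
    subjective construct (e.g., perceived violence, arousal) into a single
    corrected ground-truth time series by trusting trends over values.
    Implements signed differential agreement (SDA), banded dynamic time
    warping alignment, spectral inlier selection, trapezoidal segmented
    regression with a heuristic segment-budget search, trend voting,
    flat-region extraction, conversion of pairwise "which is lower"
    judgements into dummy-reference triplets, one-dimensional t-stochastic
    triplet embedding, and trapezoidal signal reconstruction, together with
    a sample-wise averaging baseline, evaluation against scalar reference
    ratings, and a simulator of annotator perception errors (monotone
    perception functions, overshoot, drift, lag) for verifying every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
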
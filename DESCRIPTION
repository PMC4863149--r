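Package: dtwdecode
Title: Single-Trial Word Decoding with Dynamic-Time-Warping Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decodes pairs of words from single-trial multichannel
    high-gamma (70-150 Hz) envelope features, as recorded in
    electrocorticography. Per-electrode trial-by-trial dissimilarities are
    computed by dynamic time warping to absorb onset delays and local
    stretching or compression of the neural response, turned into Gaussian
    kernels, and combined by fixed-rule multiple kernel learning with
    weights proportional to each electrode's discriminative power (ROC
    AUC of within- versus between-class realigned distances). A
    soft-margin support vector machine on the combined precomputed kernel
    is evaluated by nested leave-one-out cross-validation, with
    full-pipeline label-permutation significance testing,
    Benjamini-Hochberg multiple-comparison correction and group-level
    tests against chance. Includes a preprocessing chain (band-pass,
    notch, common average reference, Hilbert envelope, decimation,
    envelope-based speech onset detection, baseline z-scoring) and a
    synthetic trial generator with class templates, onset jitter, smooth
    monotone time warps and broadband noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
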
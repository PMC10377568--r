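Package: mrisynth
Title: Cross-Contrast Brain MRI Synthesis with Radiomic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to train and evaluate generative translation models
    between T2-weighted and FLAIR-like brain MRI slices, and to score how
    distinguishable synthetic images are from real ones.  Provides a seeded
    phantom generator of aligned cross-contrast slice pairs, fixed-bin
    intensity discretization of masked images, gray-level co-occurrence,
    run-length and size-zone texture matrices with 23 named radiomic
    features, pixel-level fidelity metrics (MAE, MSE, PSNR), and a
    per-feature statistical comparison of real versus synthetic feature
    distributions with a normality-gated choice between Welch's t-test and
    the Mann-Whitney U test.  Includes desk-scale cycle-consistent
    adversarial translation models (CycleGAN-style and a dual
    cycle-consistent semi-supervised variant) implemented with vectorized
    convolutions and hand-derived backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
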
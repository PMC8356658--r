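Package: seedsortnet
Title: Lightweight Attention CNN for Two-Class Seed Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements SeedSortNet, a lightweight convolutional network for
    sorting seed images into normal and abnormal classes: a dual-branch
    Root-module stem, inverted-residual-style Shield-blocks built from
    depthwise and pointwise convolutions, anti-aliased MaxBlurPool
    downsampling, and a grouped sub-feature space spatial attention module
    (SFSAM). Ships a deterministic parameter and multiply-accumulate
    profiler that reconciles the architecture's published model budgets, a
    seeded synthetic seed-image generator for data-free testing, a
    mini-batch SGD training loop with step learning-rate decay, and a
    binary-classification evaluation suite (confusion counts, accuracy,
    precision, recall, F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tools,
    EBImage,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
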
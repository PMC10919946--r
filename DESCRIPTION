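Package: softcca
Title: Sparse Canonical Correlation Analysis with Exact Support Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sparse canonical correlation analysis for two high-dimensional
    data blocks measured on the same samples. Sparsity is imposed by a
    rank-based soft-threshold inside an alternating NIPALS loop, so the
    number of nonzero canonical weights is fixed directly instead of being
    tuned through a penalty parameter. Includes latent-variable deflation
    for multiple components, a cumulative explained-variance measure
    adjusted for correlated components, out-of-sample canonical
    correlations by cross-validation, permutation-based significance
    testing with equal-sparsity nulls, a probabilistic-CCA simulation
    framework, broom-style tidiers and ggplot2 diagnostics, and a small
    command-line interface for delimited matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
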
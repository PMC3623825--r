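Package: pcorsel
Title: Graph-Constrained Partial Correlation Estimation and Iterative
    Gaussian Graphical Model Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates partial correlation matrices under the constraint that
    coefficients absent from a given undirected independence graph are exactly
    zero, using per-node regressions restricted to graph neighbors with
    pluggable engines (ordinary least squares, cross-validated or analytic
    ridge, partial least squares, lasso, adaptive lasso). Provides the
    iterative estimate-threshold-re-estimate procedure for Gaussian graphical
    model inference, a sparse positive-definite simulation generator
    (Erdos-Renyi and preferential-attachment graphs), reference estimators
    (shrinkage partial correlations, iterative proportional fitting for
    covariance selection), and evaluation statistics (matrix mean squared
    error, positive predictive value, sensitivity, Fleiss' kappa network
    stability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
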
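Package: i2bias
Title: Exact Bias of the I-Squared Heterogeneity Statistic in Meta-Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes Cochran's Q and the I-squared heterogeneity statistic
    from study-level meta-analytic data, and evaluates the exact expectation
    and bias of both the naive estimator 1 - df/Q and the truncated estimator
    max(0, 1 - df/Q) under homogeneity, random-effects, and fixed-effects
    models with a common within-study standard error.  Closed forms are
    expressed through upper incomplete gamma functions and real-order
    generalized exponential integrals, cross-checked by adaptive quadrature
    against the exact sampling distribution of Q and by a seeded Monte Carlo
    simulator of synthetic meta-analyses.  Includes curve tables and plots of
    the bias as a function of the number of studies, and a command-line
    interface for estimation, bias queries, curve export, and simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
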
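Package: sdotools
Title: Stochastic Dynamic Operators for Spike-Triggered Signal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-dependent, probabilistic generalization of the classical
    spike-triggered average (STA). Continuous covariate signals (e.g. EMG) are
    quantized into discrete amplitude states; the stochastic dynamic operator
    (SDO) is an n-by-n matrix mapping the pre-spike state distribution to the
    change in the post-spike state distribution. The package provides the
    direct linear SDO estimator and a constrained least-squares variant, seven
    hypothesis matrices sharing a common update rule, shuffle-based Monte
    Carlo significance tests with a Bonferroni decision rule, classical STA
    baselines (paired t-test, increment-shifted average, bootstrap-deviation),
    eight stochastic time-series generators for validation studies,
    prediction scoring (state errors, Kullback-Leibler divergence,
    log-likelihood, bootstrapped cumulative errors, Cohen's d), and
    visualization tools (STIRPD, shear and quiver operator views, motif
    classification).
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
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
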
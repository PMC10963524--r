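Package: ganpop
Title: Populations-of-Models Inference for Conductance-Based Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Solves the stochastic inverse problem of hippocampal CA1
    pyramidal-neuron excitability. Provides a compiled conductance-based
    (Hodgkin-Huxley type) simulator under current-clamp protocols,
    extraction of 13 action-potential and hyperpolarization features,
    differential-evolution calibration and Sobol variance-based parameter
    screening, a conditional generative adversarial network that performs
    amortized inference of maximal-conductance distributions from feature
    vectors, a Metropolis-Hastings benchmark sampler, and statistical
    validation machinery (two-sample Kolmogorov-Smirnov tests, Cohen's d
    effect sizes, two-group scenario enumeration and agreement scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
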
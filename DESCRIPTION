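Package: mindrace
Title: Joint Modeling of Sustained Attention and Self-Reported Mind Wandering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the Timed Racing Diffusion Model (TRDM) of go/nogo
    performance in the Sustained Attention to Response Task, structurally
    bound to a Thurstonian ordinal-probit model of thought-probe responses
    via a participant-level linking function. Provides closed-form Wald
    (inverse-Gaussian) first-passage distributions, defective response-time
    densities, hierarchical Bayesian estimation of six competing joint-model
    variants by Markov chain Monte Carlo, DIC model comparison,
    posterior-predictive checking, and a synthetic-data generator that
    emulates the designs of two SART experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
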
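Package: movestates
Title: Covariate-Driven Hidden Markov Models for Animal Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing animal telemetry with hidden Markov models:
    regularisation and filtering of GPS fix tables into step-length and
    turning-angle series, gamma and von Mises state-dependent distributions,
    multinomial-logit transition probabilities driven by landscape covariates
    (human-footprint index, protected-area membership, denning season),
    maximum-likelihood fitting with multiple starts, AIC model selection,
    Viterbi decoding, forward-backward state probabilities, delta-method
    confidence intervals for stationary state probabilities, pseudo-residual
    goodness-of-fit, a seeded synthetic-landscape and track generator, and a
    correlated-random-walk connectivity simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    lubridate,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
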
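Package: confrl
Title: Confidence-Based Value Learning in Instrumental Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood analysis of trial-wise value
    learning models for a two-alternative instrumental conditioning task with
    interleaved no-feedback phases and trial-wise confidence ratings. Provides
    a seeded generator for the block-structured task design, six learning
    models (static values, devaluation, choice-induced reinforcement,
    stimulus-specific and stimulus-unspecific confidence-prediction-error
    learning, and choice perseveration), per-subject likelihood fitting with
    AIC/BIC model comparison, model and parameter recovery studies, generative
    effect statistics, and forward power simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
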
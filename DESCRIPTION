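Package: contextRL
Title: Context-Dependent Reinforcement Learning Models for Probabilistic
    Bandit Tasks with a Transfer Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of instrumental learning in
    fixed-pair probabilistic bandit tasks where outcome valence (gain/loss),
    outcome magnitude and feedback information (partial/complete) vary across
    choice contexts, followed by a feedback-free transfer test. Implements
    five Q-learning variants that differ in how outcomes are encoded
    (absolute monetary value, context-normalized binary value, their convex
    mixture, marginally decreasing utility, or divisive normalization at the
    decision stage), subject-level maximum-likelihood fitting with BIC model
    comparison, synthetic-cohort generation with known ground truth, and the
    downstream behavioral analyses: correct-choice rates, magnitude effects,
    transfer-test preference matrices, trial-wise model evidence, posterior
    predictive checks, and parameter/model recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    Rcpp,
    rlang,
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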
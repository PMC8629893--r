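Package: revlearn3
Title: Three-Option Probabilistic Reversal Learning: Simulation, Modelling and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of a three-option probabilistic
    reversal learning task under a within-subject drug manipulation. Provides the
    task environment (feedback schedules, first-choice role assignment), an
    Experience-Weighted-Attraction (EWA) model family with forgetting and
    Pearce-Hall hybrid variants plus drug-split extensions, maximum-a-posteriori
    fitting with Laplace-approximated model evidence, hierarchical Bayesian
    model comparison with protected exceedance probabilities, posterior-predictive
    validation, the behavioural statistics pipeline (chance-corrected accuracy,
    repeated-measures ANCOVA with Huynh-Feldt handling, stay probabilities,
    parameter-change correlations), an optimal-learning-rate analysis, and a
    synthetic cohort generator with known ground truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
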
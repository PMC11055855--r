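Package: trialpe
Title: Model-Based Single-Trial ERP Analysis of Feedback Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for model-based single-trial electrophysiology in
    probabilistic feedback learning. Simulates the two-alternative
    probabilistic selection task (five stimuli with graded reward
    probabilities), fits Rescorla-Wagner Q-learning models with a single
    learning rate, valence-specific (choice-confirmation) learning rates,
    or additional counterfactual updating of the unchosen option, and
    compares them by negative log-likelihood and BIC. Trial-level
    unsigned prediction errors from the winning model are related to
    single-trial FRN/RewP and P300 amplitudes -- quantified from epoched
    EEG via baseline correction, zero-phase filtering, threshold-based
    artifact rejection, difference-wave peak detection and windowed mean
    amplitudes -- using crossed-random-effects linear mixed models with
    stepwise term selection, Satterthwaite degrees of freedom, simple
    slopes and simulation-based power analysis. A synthetic-data module
    generates behaviour, single-trial amplitudes and noisy epochs with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
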
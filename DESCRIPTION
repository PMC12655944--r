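Package: comafusion
Title: Multimodal CNN-LSTM Models with Genetic-Algorithm Optimization for
    EEG-Based Coma Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the outcome (survival versus death) of
    comatose patients from multichannel EEG recordings fused with clinical
    covariates. Provides a synthetic comatose-EEG cohort generator with
    band-limited spectral structure and a plantable outcome effect,
    time-domain and one-hot patient featurization behind a stable feature
    registry, a hierarchical-fusion CNN-LSTM classifier implemented with a
    self-contained matrix-based neural-network engine, a mixed-type genome
    (binary feature mask plus grouped hyperparameter genes) evolved by a
    genetic algorithm with tournament selection, two-point crossover and
    typed mutation operators, and a patient-grouped evaluation protocol with
    stratified hold-out, five-fold cross-validation and nine-segment
    majority voting.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
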
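# comafusion

Predicting the outcome of comatose ICU patients — survival (`favorable`)
versus death (`unfavorable`) — from multichannel EEG fused with clinical
covariates. The package is written for clinical-neurophysiology and
biomedical-ML researchers who want a fully reproducible, desk-scale
implementation of a multimodal CNN-LSTM classifier whose features and
hyperparameters are jointly optimized by a genetic algorithm, together
with a synthetic comatose-EEG cohort generator that makes the entire
pipeline testable without access to any hospital data.

## The model

Each patient contributes ten 2-s EEG segments on a 20-channel 10-20
montage. For an EEG batch `X_EEG (B × T × C)`:

- stacked 1-D convolutions + max pooling over time give a feature map
  `F_CNN (B × T' × D_CNN)`;
- stacked LSTMs reduce it to a latent vector `H_LSTM (B × D_LSTM)`
  (final hidden state of the last layer);
- the latent state is concatenated with auxiliary features — the patient
  vector `X_P` (age + one-hot sex + one-hot etiology, 14 features) and
  per-channel time-domain statistics `X_TD` (mean, min, max, std, var;
  100 features) — giving `Z_fusion (B × (D_LSTM + D_P + D_TD))`;
- a dense stack ends in a 2-way softmax.

A mixed-type chromosome (one selection bit per auxiliary feature + grouped
hyperparameter genes for the convolution/LSTM/dense/training blocks) is
evolved by a GA — binary tournaments, two-point crossover (p = 0.6),
per-gene mutation at rate 2/n with flip / window / categorical operators —
whose fitness is the macro F1 of segment-level validation predictions.
Patients are evaluated by majority vote over their first nine segment
predictions, under a stratified patient-grouped 40/40/20 hold-out and
patient-level stratified 5-fold cross-validation.

The neural networks run on a self-contained matrix-based engine (no
external deep-learning framework); training is deterministic given a seed.
See the methods vignette (`vignettes/comafusion-methods.Rmd`) for the full
model description, design decisions and limitations.

## Worked example

Generate a small synthetic cohort with a planted outcome effect, and
compare the multimodal fusion model against a time-domain-only MLP under
patient-level 5-fold cross-validation:

```r
library(comafusion)
library(dplyr)

cfg <- cohort_config(
  n_patients = 30, segments_per_patient = 10, sampling_rate = 100,
  etiology_outcome_counts = tibble::tibble(
    etiology   = c("Stroke", "Metabolic Coma"),
    favorable  = c(150, 0),
    unfavorable = c(0, 150)),
  sex_counts = c(male = 15, female = 15),
  effect_size = 1.1,            # 10% amplitude ratio on T6/F4/T4/O2/FZ/CZ
  seed = 21)
cohort <- generate_cohort(cfg)
cohort
#> <eeg_cohort> 30 patients, 300 segments (100 Hz, 2 s)

spec <- architecture_spec(
  conv_layers = list(list(filters = 8, kernel_size = 5, pool_size = 4,
                          activation = "relu")),
  lstm_layers = list(list(units = 16)),
  dense_layers = list(list(units = 16, dropout = 0)),
  training = list(learning_rate = 1e-3, batch_size = 16, epochs = 10,
                  optimizer = "adam"))

roster <- list(
  cnn_lstm_patient_td = list(type = "fusion", blocks = "both"),
  mlp_td              = list(type = "mlp",    blocks = "td"))

res <- run_comparison(cohort, roster, fusion_spec = spec,
                      split = NULL, cv = cv_spec(n_folds = 5, seed = 3),
                      seed = 17)
summarize_comparison(res)
#> # A tibble: 2 × 10
#>   model               scheme accuracy_mean accuracy_sd f1_macro_mean f1_macro_sd
#>   <chr>               <chr>          <dbl>       <dbl>         <dbl>       <dbl>
#> 1 cnn_lstm_patient_td cv             0.967      0.0745         0.966      0.0767
#> 2 mlp_td              cv             0.733      0.149          0.697      0.215
#>   precision_mean precision_sd recall_mean recall_sd
#>            <dbl>        <dbl>       <dbl>     <dbl>
#> 1          1            0           0.933     0.149
#> 2          0.733        0.435       0.533     0.298
```

The fusion model classifies 96.7% of held-out patients correctly (macro
F1 0.966 averaged over folds): the planted 10% amplitude ratio reaches it
through the time-domain features and the age–outcome shift through the
patient block. The deliberately conservative MLP baseline (learning rate
1e-4, 30 epochs) learns the same time-domain features only partially
(macro F1 ≈ 0.70). Metrics are patient-level, with `unfavorable` as the
positive class.

A GA search over features and hyperparameters runs through
`optimize_coma_model()`; its per-run feature-selection masks aggregate
into a frequency report (`aggregate_runs()`, `plot_feature_frequency()`)
showing which auxiliary features the wrapper selection keeps.

A thin command-line wrapper is installed as `exec/comafusion` with
`simulate`, `evaluate` and `optimize` subcommands.

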
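---
title: "Methods: multimodal CNN-LSTM models with genetic-algorithm optimization for coma-outcome EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal CNN-LSTM models with genetic-algorithm optimization for coma-outcome EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comafusion)
```

## The problem and the model

`comafusion` predicts the outcome of comatose ICU patients — `favorable`
(survival) versus `unfavorable` (death) — from short multichannel EEG
segments fused with clinical covariates. Each patient contributes ten 2-s
segments recorded on a 20-channel 10-20 montage; comatose EEG concentrates
its power in the delta and theta bands (1–7 Hz).

The classifier is a *hierarchical fusion* network. Writing the EEG input
as $X_{\mathrm{EEG}} \in \mathbb{R}^{B \times T \times C}$ (batch, time
samples, channels):

1. A stack of one-dimensional convolutions over the time axis, each
   followed by max pooling, extracts a reduced temporal feature map
   $F_{\mathrm{CNN}} \in \mathbb{R}^{B \times T' \times D_{\mathrm{CNN}}}$.
   Channels enter as input depth; convolutions use "same" padding with odd
   kernels, so only pooling shortens the time axis.
2. Stacked LSTM layers consume the feature map; the final hidden state of
   the last layer is the latent representation
   $H_{\mathrm{LSTM}} \in \mathbb{R}^{B \times D_{\mathrm{LSTM}}}$
   (intermediate LSTM layers pass on their full sequences).
3. Auxiliary features — the patient vector $X_P$ (age, one-hot sex,
   one-hot etiology; 14 features under the default schema) and the
   time-domain vector $X_{TD}$ (per-channel mean, min, max, standard
   deviation, variance; 100 features) — are concatenated with the latent
   state: $Z_{\mathrm{fusion}} = [H_{\mathrm{LSTM}} \,\|\, X_P \,\|\, X_{TD}]$,
   so the first dense layer's input width is exactly
   $D_{\mathrm{LSTM}} + D_P + D_{TD}$. This identity is asserted by
   introspection every time a model is built and is exposed in the model's
   `$contract`.
4. A dense stack ends in a 2-way softmax; training minimizes
   cross-entropy. With no auxiliary features the same code is the EEG-only
   CNN-LSTM baseline.

The network is implemented in a self-contained matrix-based engine
(`R/nn-engine.R`): im2col convolutions, max pooling with argmax routing,
LSTM backpropagation through time, inverted dropout, and Adam, RMSprop and
plain SGD updates. Backpropagation was verified against central finite
differences during development. All randomness — initialization, shuffling,
dropout — draws from R's stream, so building with a seed and training with
a seed reproduces a model bit-for-bit.

The comparison MLPs use one hidden layer as wide as their input, a single
sigmoid output interpreted as the probability of `unfavorable`, binary
cross-entropy loss, and Adam at learning rate $10^{-4}$ for 30 epochs.

## The genome and the genetic algorithm

A chromosome has a binary part 1 (one selection bit per feature in the
registry: patient block first, then the channel-major time-domain block;
114 bits for the default schema) and grouped hyperparameter genes (part
2a–2d: convolution, LSTM, dense, and training genes). Variable layer counts
are encoded as explicit depth genes plus maximal slot blocks; slot genes
beyond the active depth are carried but ignored by decoding. This keeps the
chromosome length fixed, so two-point crossover is always well-defined, at
the cost of some neutral genetic material.

The GA uses binary tournaments (ties resolved uniformly), two-point
crossover with probability 0.6, and per-gene mutation with probability
$2/n$: boolean genes flip; ordered genes mutate by a *window* draw among up
to two neighbors on each side of the current value in the sorted domain,
current value excluded; nominal genes redraw uniformly among the *other*
categories, which makes a two-level nominal gene behave exactly like a
boolean one. Window radius (default 2) is configurable. Fitness is the
macro F1 of segment-level validation predictions of the decoded, trained
model; chromosomes whose pooling chain collapses the time axis, or whose
training diverges to a non-finite loss, score 0 so evolution continues.
Replacement is elitist: each generation produces `population_size -
elitism` offspring, parents and offspring are pooled, and the best
`population_size` individuals survive (a $(\mu + \lambda)$-style
truncation, which guarantees a non-decreasing best fitness; the default
reserves 2 slots). Survivors keep their stored fitness; they are not
re-evaluated. An optional
hash-keyed fitness cache skips retraining duplicated chromosomes; disabling
it reproduces the full training budget of at most
$N_{pop} \times (N_{gen} + 1)$ model fits per run.

The exact hyperparameter domains of the original search are not public;
`make_default_schema()` therefore ships desk-scale domains (filters 8–64,
kernels 3–11, pools 2/4, LSTM units 16–128, dense units 16–128, dropout
0–0.4, learning rate $10^{-4}$–$3\times10^{-3}$, batch 8–32, epochs 5–15,
Adam/RMSprop/SGD, ReLU/tanh/ELU) and the schema is fully user-definable and
JSON-serializable. Real-valued hyperparameters are discretized into ordered
domains because the window mutation presupposes an ordered finite set.

## The synthetic cohort generator

The study's hospital data are private, so the package ships a generator
whose defaults replicate the reference cohort's composition: 60 patients
with 10 two-second segments each (600 segments), the etiology-by-outcome
segment table of `reference_etiology_counts()` (300/300 class balance, e.g.
170 favorable traumatic-brain-injury segments), ages 49.16 ± 19.18 years
(truncated normal on 18–95), and 44 males / 16 females. Each synthetic
patient carries one etiology and one outcome; segment counts divide by the
10 segments per patient, and an indivisible cell is an explicit error.

Signals are sums of band-limited sinusoids (3 per band, random frequencies
and phases per channel) plus white noise; normalized band weights equal the
band's share of sinusoidal power, and the default comatose profile puts
85% of that power below 7 Hz. Two planted, configurable class effects make
the outcome learnable: an amplitude ratio (`effect_size`, default 1.5) on
right-anterior/central channels (T6, F4, T4, O2, FZ, CZ — the electrode
group the wrapper selection is expected to rediscover), applied to the
whole channel so the class RMS ratio is exact in expectation; and an
age–outcome shift (default 10 years between class means, overall mean
preserved) reflecting the clinically expected poorer recovery of older
patients. `effect_size = 1` with shift 0 plants nothing. How outcome
manifests in real comatose EEG is unknown; the planted effects are modeling
choices that give the pipeline something recoverable, not claims about the
physiology.

What the generator does *not* emulate: 1/f background spectra, artifacts,
inter-channel coherence structure, non-stationarity, or per-patient
sampling-rate heterogeneity (one configurable rate per cohort, default
250 Hz; the loader pads or truncates to a fixed tensor length because the
network needs fixed shapes). Passing tests on this cohort therefore
demonstrate the pipeline's mechanics — counts, contracts, recoverability of
planted structure — not clinical performance.

## Numerical and protocol choices

* **Variance convention**: population (divide by $N$) for time-domain
  features and scalers.
* **Scaling**: auxiliary features are standard-scaled with statistics
  fitted on the training partition only; zero-variance features clamp
  their scale to 1 (constants scale to 0). Raw EEG is z-scored per segment
  and channel before the CNN (flag `scale_eeg`); note this deliberately
  removes absolute amplitude from the EEG branch, so planted amplitude
  effects reach the model through the time-domain features and the
  auxiliary pathway.
* **Class conventions**: class order is (`favorable`, `unfavorable`);
  probability ties predict `favorable`; `unfavorable` is the positive
  class for precision/recall (the clinical detection target);
  zero-denominator precision/recall score 0.
* **Protocol**: the hold-out split is 40/40/20 stratified by outcome and
  patient-grouped by default (`unit = "segment"` reproduces the literal
  segment-level protocol, which permits within-patient leakage); CV is
  patient-level stratified 5-fold; only segments 0–8 of each patient enter
  classification, and each patient's label is the majority vote of its
  nine segment predictions (nine binary votes cannot tie). The tenth
  segment is generated and stored but excluded from evaluation.
* **GA seeds**: replicate run $i$ uses `base_seed + i`; each chromosome's
  training seed mixes a chromosome hash with the base seed, so cached and
  recomputed fitness agree.

## Problem sizes used by the shipped tests

The test suite exercises every protocol at sizes a single CPU handles in
minutes, as the package's own verification scale: the full 600-segment
replication cohort for all count checks; 100 Hz, 200-sample cohorts of
20–30 patients for training-based checks; a 20-bit count-ones surrogate
(population 30, 30 generations, 10 runs) for GA convergence; 6 reduced GA
runs (population 10, 10 generations, a single-block tiny network family at
8 training epochs) for planted-feature recovery, with six planted
auxiliary features (age plus five channel-std features, 1.2-sd class
shift) tested against background by a one-sided rank test — the shift is
deliberately mild so that selecting *additional* planted features keeps
improving fitness, and the cohort's etiologies are balanced across
outcomes so no clinical covariate leaks the label; and a 30-patient cohort
with amplitude ratio 1.1 for the five-fold CV comparison, where the
multimodal fusion model must reach macro F1 ≥ 0.90 and beat the
time-domain-only MLP. The ratio 1.1 was chosen as a mild effect that the
properly trained fusion model separates cleanly while remaining hard for
the deliberately low-learning-rate MLP baseline.

## Known limitations

* Only basic time-domain features are implemented; frequency-domain and
  nonlinear descriptors are out of scope, as is reading clinical EEG file
  formats (EDF/BrainVision).
* The fitness is macro F1 alone; no model-complexity penalty or
  multi-objective formulation is implemented.
* The engine is CPU-bound plain R; it is sized for desk-scale experiments,
  not GPU-scale training.
* Cohort serialization uses plain CSV (one long table of signals), which
  is simple and portable but not compact.
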
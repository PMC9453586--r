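---
title: "Forecasting near-future abnormal lab values: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting near-future abnormal lab values: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labforecast)
```

## The problem

Laboratory values of critically ill patients — here a panel of 25 analytes
relevant to mechanically ventilated ICU patients — are measured irregularly,
sparsely, and with occasional gross recording errors. The task this package
addresses is *multilabel next-step classification*: given a patient's recent
history on a 4-hour grid plus three demographic covariates (age, sex,
weight), predict which of the 25 channels will be **outside its reference
range** at the next 4-hour step. Each channel contributes one binary label
(0 = normal, i.e. inside the closed interval `[normal_low, normal_high]`;
1 = abnormal), so the target is a length-25 binary vector.

The 4-hour grid is the package's fundamental time unit because most ICU lab
channels are redrawn roughly every 4 hours; stays span 12–72 hours, i.e.
3–18 grid steps.

## Synthetic cohorts

Real ICU extracts are access-restricted, so the package ships a generator
whose output has the same *statistical shape* and feeds the identical CSV
schema a real extract would (`measurements.csv`: stay, channel, time,
value; `demographics.csv`: age, sex, weight). Per channel, the latent
dynamics are:

* a mean-reverting AR(1) fluctuation around `baseline_mean` with stationary
  standard deviation `baseline_sd` and lag-1 autocorrelation
  `ar_coefficient`;
* a two-state Markov **episode** process: each step, an out-of-episode
  channel enters an abnormal episode with probability `episode_rate` and an
  in-episode channel remains with probability `episode_persistence`. While
  in episode, a drift places the latent mean beyond the reference bound in
  the channel's characteristic direction of derangement
  (`episode_direction`: lactate rises, hemoglobin falls, ...) by a quarter
  of the range width plus three standard deviations, so in-episode values
  are abnormal with near-certainty. Directional episodes matter for the
  Tukey step downstream: they keep the abnormal mass (stationary fraction
  `rate / (rate + 1 - persistence)`, 1/3 under the defaults) concentrated
  in one tail, where it is large enough that the cohort-wide quartiles
  reach into it and the fences separate genuine abnormality from gross
  recording errors.

Episodes are what make the task learnable: abnormality persists, so the
recent past predicts the near future. The stationary in-episode fraction
of the chain is used as the initial state distribution; for the absorbing
case `persistence = 1`
(no stationary law) stays start in-episode with probability 1/2 to keep the
label classes balanced. Observations are the latent grid values plus
Gaussian observation noise (`obs_noise_sd`, in units of the channel's
`baseline_sd`), recorded at each channel's cadence (4/8/24 h in the default
panel) with uniform timing jitter. Corruption is then layered on
explicitly, with ground truth retained: Bernoulli dropout per measurement
(`missing_prob`) and, with probability `outlier_prob`, replacement by
`baseline_mean ± multiplier × range width` — a transcription-error-scale
outlier whose location is recorded so detection recall can be scored.

A second hospital ("cohort B") is emulated by shifting every channel's
baseline by a configurable multiple of its `baseline_sd` and raising its
missingness rate: the same physiology, different calibration and
documentation practice. Optional cross-channel coupling (an episode in a
source channel raising a target channel's entry rate) is available but off
by default.

**What the generator does not emulate.** Channel cross-correlation at the
value level, treatment feedback, age/severity interactions, and realistic
per-channel marginals. Absolute accuracies on synthetic cohorts are
therefore *not* comparable to accuracies on real extracts, even where they
happen to land in a similar range. Passing tests certify the machinery
(preprocessing correctness, learnability, reproducibility, the direction
of the cross-cohort gap), not clinical performance.

## Preprocessing

The chain converts sparse irregular measurements into complete matrices,
in this order:

1. **Discretize** — bin `m` covers hours `[4m, 4m + 4)` (0-based, so `X_0`
   is at admission); the latest measurement in a bin wins, because the most
   recent value is the clinically operative one.
2. **Hold-time estimation** — per channel, pool all consecutive
   inter-measurement gaps across stays; the hold time is the smallest gap
   at which the cumulative count fraction reaches `coverage_threshold`
   (default 0.9), rounded to the nearest positive multiple of the grid
   step. The default 0.9 captures the dominant cadence while tolerating
   rare long gaps. The table is estimated on the *training* cohort only and
   reused on any other cohort scored against it (leakage hygiene).
3. **Sample-and-hold** — each observation is carried forward until the next
   observation or until the hold horizon lapses: the cell `j` steps later
   is filled iff `j × step_hours ≤ hold_time`. Beyond that a stale value is
   treated as corrupted and the cell stays missing. Observed cells are
   never overwritten; filling never runs backward.
4. **Tukey outlier removal** — per-channel quartiles over all observed and
   held cells cohort-wide (linear interpolation between order statistics,
   i.e. `quantile(type = 7)`); cells outside `[Q1 − k·IQR, Q3 + k·IQR]`
   (k = 1.5) are blanked back to missing. Fence membership is closed so a
   constant channel (IQR 0) loses nothing. Cohort-wide rather than per-stay
   quartiles: with at most 18 rows per stay, per-stay quartiles are far too
   unstable. Outlier removal runs *before* imputation — deleting after
   imputation would recreate holes — so one imputation pass closes
   everything.
5. **Stay filtering** — stays with a missing fraction *strictly* above 0.5
   (after sample-and-hold) are discarded; a stay at exactly 0.5 is kept.
6. **Imputation** — k-nearest-neighbour (k = 5) over stacked stay-time
   rows: each incomplete row finds its nearest complete rows by Euclidean
   distance over its observed, z-scored channels and takes their mean;
   rows with no usable neighbours fall back to the cohort channel mean. An
   optional SVD pass then iterates rank-`r` reconstruction over the imputed
   cells (classic low-rank completion), so an exactly low-rank matrix is
   recovered to numerical precision. For tractability the donor pool is
   capped at 1000 complete rows (deterministic, evenly spaced thinning);
   beyond that size the gain in neighbour quality is negligible.

Every cell carries a provenance mask (`observed`, `held`, `imputed`,
`missing`) throughout, and the pipeline's contract — checked by tests on
every generator configuration — is zero missing cells and finite values.

## Windows, labels, splits

A window of `W` consecutive steps (default 6, i.e. 24 h of history)
predicts the binarized values at the step immediately after it. A stay of
`L ≥ W + 1` steps yields `L − W` samples; a short stay (`2 ≤ L ≤ W`)
yields one sample, left-padded with zero rows, targeting its last step; the
progressively-padded alternative (several samples per short stay) was
rejected to avoid overweighting short stays. Windows from all stays are
pooled and shuffled before splitting 68/12/20 (largest-remainder rounding),
so windows of one stay can land in different partitions — deliberately
matching the evaluation design this package reproduces; a patient-grouped
split would be stricter and is intentionally not the default. Inputs are
z-scored with training-partition statistics (padding rows excluded and kept
at exactly zero); demographics are encoded (sex → 0/1) and z-scored the
same way. Labels are always computed from raw channel units, never from
normalized values. Boundary values count as normal: "out of range" is read
as strict exceedance.

## The six predictor families

All sequence models share one topology contract: the lab-value window is
encoded by the sequence module, demographics are concatenated *after*
encoding (late concatenation), and a ReLU dense layer feeds a sigmoid
output of width 25. Training minimizes mean binary cross-entropy with Adam
(mini-batches of 64). Because no deep-learning framework is assumed, the
forward and backward passes are implemented in the package itself in plain
array arithmetic; every backward pass is verified against central-difference
numerical gradients in the test suite (relative error below 1e-4).

* **LSTM** — one tanh LSTM layer (48 units); the final hidden state passes
  through batch normalization before concatenation.
* **CNN** — one valid 1-D convolution along time (48 filters, kernel 3,
  leaky ReLU), flattened.
* **M-CNN** — two parallel convolutional streams with kernel sizes 2 and 4
  (32 filters each), capturing short- and long-range temporal patterns;
  their flattened outputs are concatenated before the head.
* **Transformer** — each step is concatenated with a learned time encoding
  (one affine component plus sinusoids with learned frequencies and
  phases), projected to width 32 by a per-step dense map (a 1×1 temporal
  convolution), passed through one two-head self-attention block and a
  per-step ReLU dense layer, then mean-pooled over time. Residual paths
  and layer normalization are omitted: at depth one they are not needed
  for stable optimization.
* **TCN** — three causal dilated convolutions (dilations 1, 2, 4, kernel
  2, 32 filters, leaky ReLU), length-preserving via left zero padding; the
  last time step of the final layer — which by causality sees the whole
  window — is the sequence feature.
* **Gradient boosting** — one binary boosted-tree classifier per label
  (one-vs-rest, xgboost backend) on the flattened `W × 25 + 3` feature
  vector; 200 rounds, depth 6, learning rate 0.1. A label constant in
  training degenerates to its prior probability, flagged but not fatal.

Layer widths are deliberately small: the reference systems tuned
hyperparameters with a search library whose selected values are not
published, so this package fixes readable, desk-scale defaults
(overridable per architecture) and treats reproducibility as the priority.
The GRU cell variant was considered and not included; the recurrent family
is LSTM-only.

**Early stopping.** Training stops when the validation loss has failed to
improve on its running best by at least `min_delta = 0.01` for
`patience = 10` consecutive epochs (the first epoch seeds the running best
and counts as non-improving). "Change" is interpreted as *improvement over
the running best* — standard min-delta semantics — rather than absolute
epoch-to-epoch change; the rule is exposed as a pure function and tested
against hand-simulated traces (a constant loss stops at epoch 10 exactly).

**Decision threshold.** A label is called abnormal iff its predicted
probability strictly exceeds `th = 0.5`; a probability exactly at the
threshold is normal, which keeps the degenerate `th → 1` limit all-zeros.

## Evaluation

Metrics are micro-averaged: true/false positives/negatives are pooled over
every `(sample, label)` cell before computing accuracy
`(TP+TN)/total`, precision, recall and F1. "Accuracy" is per-cell binary
accuracy, not subset (exact-match) accuracy. Divisions by zero yield 0 with
an explicit flag. The implementation is tested against an independent
per-cell double-loop oracle to 1e-12 over a thousand random configurations.

The two-cohort experiment mirrors training on one hospital system and
testing on another: for each direction, the model trains and early-stops on
cohort X's train/validation splits and is scored on (a) X's held-out test
split and (b) the *entire* sample set of the other cohort, preprocessed
with X's hold times and normalized with X's statistics. (Scoring the other
cohort in full, rather than a test split of it, follows from the sample
accounting of the design being reproduced.) The qualitative expectation —
checked over repeated seeds for the M-CNN — is that within-cohort accuracy
is at least cross-cohort accuracy; only the *direction* of the gap is
asserted, since its size depends on how hard the configured shift is.

## Numerical and reproducibility choices

* One experiment-level seed drives everything; stage seeds are derived by
  hashing stage labels (`derive_seed`), so no two stages share a stream.
* Training, prediction and the full comparison harness are bitwise
  reproducible under single-threaded execution; this is tested.
* BCE probabilities are clipped at 1e-12 before the log; a non-finite
  training loss aborts with the epoch and batch named.
* Quartiles use `type = 7` interpolation; z-score denominators of constant
  features fall back to 1; batch normalization uses variance floor 1e-5.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while staying desk-scale: the
learnability benchmark uses 300–500 stays (≈ 2,900–4,900 windows, 25
channels, W = 6) and 30 training epochs per architecture; the outlier-recall
check uses 200 stays; the cross-cohort gap uses 60 stays per cohort over
3–5 seeds. These sizes were chosen as the smallest at which the measured
quantities are stable across seeds.

## Known limitations

* Synthetic dynamics are per-channel (no value-level cross-correlation by
  default), so multivariate imputation gains are modest on generated data.
* Architecture *rankings* on generated cohorts are not informative about
  real data; the harness is for correctness and generalization-direction
  checks, not model selection.
* The minority sampling cadences (8 h, 24 h) are configurable but their
  real-world mixture is unknown; the defaults are a guess.
* No hyperparameter search, no GPU paths, no regression-then-threshold
  mode (direct binary classification is the only objective).
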
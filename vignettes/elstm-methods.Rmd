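---
title: "Ensembles of LSTM classifiers for clinical time-series outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of LSTM classifiers for clinical time-series outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Critically ill patients accumulate dozens of daily measurements — vital
signs, laboratory values — over an ICU stay, and the clinical question is a
binary one: will this patient survive the next weeks? A single recurrent
classifier can learn temporal structure in such data, but ICU cohorts are
heterogeneous (many disease patterns, strong class imbalance, heavy
missingness), and a single network fitted to all of it carries high variance.
`elstm` implements the ensemble answer: many small LSTM classifiers, each
trained on a *bootstrap resample* of the patients and a *random subspace* of
the variables, whose sigmoid outputs are averaged into one risk score.

## Data model

Each patient is a matrix $V \in \mathbb{R}^{D \times T}$ of $D$ variables
sampled once per day over $T$ days, with an observed-mask and a binary label
$Y$ (1 = death within the follow-up window). A cohort additionally carries
the class ratio $\gamma = N_{neg}/N_{pos}$; in the motivating 28-day ICU
mortality cohort (18,415 stays, 50 variables, 10 days) $\gamma \approx 7.5$.

### Preprocessing

Missing entries are filled per patient and per variable by linear
interpolation between the nearest observed days. Two choices here are not
forced by the method and are documented as this package's decisions:

* **Edge gaps** are extended from the nearest observed value (constant
  extrapolation); interpolating would require a second anchor that does not
  exist.
* **Order**: imputation happens first, then normalisation statistics are
  fitted on the *imputed* training data. A variable a patient never had
  measured is filled with the training mean of that variable — equivalently
  0 after z-scoring, the least-informative neutral value.

Normalisation subtracts per-variable means and divides by per-variable
standard deviations pooled over all patients and days of the training fold
only. The *sample* (n−1) denominator is used, standard deviations are
floored at $10^{-8}$ so constant variables map to 0, and the fitted
statistics are stored inside the model so test-time preprocessing is
bit-for-bit reproducible.

## The base classifier

Each base learner is a single-layer LSTM. With input $x_t$ and the
concatenation $z_t = [h_{t-1}, x_t]$:

$$f_t = \sigma(w_f z_t + b_f), \quad i_t = \sigma(w_i z_t + b_i), \quad
  o_t = \sigma(w_o z_t + b_o),$$
$$C_t = f_t \ast C_{t-1} + i_t \ast \tanh(w_c z_t + b_c), \qquad
  h_t = o_t \ast \tanh(C_t),$$

starting from $h_0 = C_0 = 0$ (the conventional choice), with a sigmoid
read-out on the final hidden state, $\tilde y = \sigma(w_{ho} \cdot h_T +
b_{ho})$.

Training minimises the class-weighted cross-entropy
$$\mathcal{L} = \tfrac1n \sum_i \big[ -\gamma\, y_i \log \tilde y_i
  - (1-y_i) \log (1-\tilde y_i) \big],$$
i.e. positives are weighted by the full training cohort's $\gamma$ and
negatives by 1 — the standard construction for this weighting scheme; scores
are clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss so it stays finite.
Optimisation is Adam (canonical moments $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) at learning rate 0.01, full-batch by default (the
training recipe names no batch size; a mini-batch size is configurable, with
seeded shuffling). Weights are Glorot-uniform initialised, biases zero.
Dropout of rate 0.5 is applied to the input layer during training only, with
masks resampled independently at every time step (whether the original
recipe resampled per step or per sequence is unknowable from its
description; per-step is the common implementation) and inverted-dropout
scaling at train time.

Two epoch policies coexist deliberately:

* **Ensemble members** train for exactly 100 epochs (bias control — the
  bagged ensemble, not a validation set, controls variance).
* The **single-LSTM baseline** trains for up to 100 epochs and returns the
  parameters from the epoch with the lowest loss on a stratified 10%
  validation split.

`train_settings(early_stop = )` switches between the two. The validation
split is stratified by label so both classes are always present — necessary
at desk scale, harmless at cohort scale.

The forward pass, backpropagation through time and Adam all live in
compiled C++ (RcppArmadillo) for speed; a plain-R `lstm_step()` /
`lstm_forward()` pair defines the recurrence independently of the compiled
path, and the test suite holds both to a scalar hand-written oracle and the
gradients to finite differences.

## The ensemble

`make_subsets()` pairs, for each of $P$ learners, a bootstrap resample of
the $N$ training patients (size $N$, drawn with replacement — standard
bagging) with a uniformly random subset of $m$ of the $D$ variables.
Reference-scale defaults are $P = 200$ and $m = D/2$ (the usual
random-subspace recommendation); both are tunable for sweep studies.
Prediction averages the base scores with equal weights:
$\tilde Y = \tfrac1P \sum_p \tilde y_p$ — no trimming, no learner
weighting.

Further decisions where the method description is silent:

* $\gamma$ is computed **once from the full training cohort**, not per
  bootstrap subset — it is defined on the training set before subsetting.
* A bootstrap resample containing a single class is redrawn (up to 100
  attempts); the weighted loss is undefined without positives.
* One shared normalisation is fitted on the full training cohort rather
  than per-subset.
* Learner $p$'s seed is a stable mix of the master seed and $p$, so results
  are independent of training order (learners could be trained in parallel)
  and growing $P$ never perturbs existing learners.

## Dynamic daily prediction

At the bedside, data arrive day by day while the model wants complete
$T$-day sequences. `predict_daily()` therefore scores, for every cutoff day
$k$, the series whose days $1..k$ are real and whose later days repeat the
day-$k$ value of each variable (last observation carried forward). The same
trained model is reused for every $k$; nothing is retrained per day.
Padding copies the *imputed* day-$k$ values — deterministic and simple;
whether the original procedure padded raw or imputed values is not stated.
The day-$T$ score equals the static prediction by construction.

## Evaluation

AUROC is the Mann–Whitney statistic (ties counted half), computed at every
distinct score; the suite verifies it against exhaustive pair enumeration.
AUPRC uses the step-wise average-precision rule, since trapezoidal
interpolation in PR space is optimistic. Thresholded metrics (sensitivity,
specificity, accuracy, precision, F1) use predicted-positive iff score ≥
threshold with a default cutoff of 0.5; how the original study thresholded
its scores is not recorded, which is the single largest barrier to
reproducing its thresholded metrics and the reason the cutoff is exposed
everywhere. `run_experiment()` repeats stratified train/test splits
(reference scale: 50 repeats, 90/10), refits preprocessing on each training
fold only, and emits per-repeat rows so any statistics package can consume
them; significance testing is intentionally out of scope.

Because the first $P$ learners of a larger ensemble *are* the ensemble of
size $P$ (per-learner seeding, equal-weight averaging), the ensemble-size
sweep is computed from one fit per split by prefix-averaging the per-learner
score matrix.

## The synthetic benchmark

The motivating cohort is a credentialed-access clinical database and cannot
ship with the package, so `generate_cohort()` provides a generator with the
same *structure*: Bernoulli labels at a 7.5:1 expected negative:positive
ratio, stationary AR(1) trajectories (lag-1 autocorrelation 0.5, unit
innovation SD) for temporal dependence, a class signal in which the first
$D/2$ variables of positive patients drift upward by `effect_size` per day
from `signal_onset_day` onward, and 10% missing-completely-at-random
entries. AR(1)-plus-drift is the simplest process offering both temporal
structure (what the LSTM exploits) and redundant informative features (what
the random subspace exploits); informative variables sit at known indices so
subset-signal overlap is controlled in tests.

What it does **not** emulate: real physiology (reference ranges, units),
cross-variable correlation, informative missingness, or measurement
artefacts. Green tests on this benchmark demonstrate the *mechanics* —
correct recurrence, gradients, aggregation, padding and metrics, and the
qualitative ensemble-versus-single ordering — not clinical-grade
performance on real ICU data.

Desk-scale study sizes, chosen so the full suite runs in minutes on one
CPU: $n = 600$, $D = 12$, $T = 10$, $P = 20$, hidden size 16, 50 training
epochs per learner, 10 repeated 90/10 splits. The default `effect_size` of
0.3 per day was fixed so that a *late* onset (day 8, three drift days —
the dynamic-prediction study) still yields a clearly detectable day-10
signal; with the default day-1 onset the benchmark is consequently an easy
problem on which both model families approach ceiling AUROC, and the
ensemble-versus-single comparison there reads as "no worse", not "better".
Paper-scale defaults ($P = 200$, $H = 64$, 100 epochs, 50 repeats) remain
the function defaults throughout.

## Known limitations

* Single-layer unidirectional LSTM only; no GRU, stacking, bidirection or
  attention, and no GPU path — desk-scale CPU is the contract.
* Daily padding carries the last value forward; no model-based forecasting.
* The dynamic evaluation imputes each series once in full before padding,
  so interpolated values before day $k$ may draw on later observations;
  a strictly causal variant would re-impute per cutoff.
* The synthetic generator's independence assumptions (across variables and
  patients) understate the difficulty of real cohorts.
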
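# elstm — bagged LSTM ensembles for clinical time-series outcomes

`elstm` predicts a binary outcome (the motivating case: 28-day ICU
mortality) from multivariate clinical time series — `D` variables measured
once per day over `T` days per patient. Instead of one recurrent network, it
fits an **ensemble of LSTM classifiers**: each base learner trains on a
bootstrap resample of the patients and a random subset of the variables
(bagging + random subspace method), and the ensemble score is the plain
average of the base sigmoid outputs,

  Ỹ = (1/P) Σₚ ỹₚ,  ỹₚ = σ(w_ho · h_T + b_ho),

where `h_T` is the final hidden state of the standard forget/input/output
gated LSTM recurrence run over the patient's sequence. Class imbalance is
handled by weighting positive instances with γ = N_neg/N_pos in the
cross-entropy loss. Because clinical data arrive day by day, the package
also provides **dynamic prediction**: a partially observed stay is padded
forward with the latest available values and scored by the same
full-sequence model, yielding an updated risk estimate every day.

The package includes the full preprocessing pipeline (linear-interpolation
imputation, training-fold z-scoring), threshold-free (AUROC, AUPRC) and
thresholded metrics, a repeated train/test-split experiment harness with
ensemble-size and subset-size sweeps, a synthetic cohort generator for
working without access to restricted clinical databases, plain-text model
bundles, and a command-line interface. The LSTM forward pass,
backpropagation through time and the Adam optimiser are implemented in
C++ (RcppArmadillo); training an ensemble of 20 desk-scale learners takes
well under a minute on one CPU core.

## Worked example

```r
library(elstm)

# synthetic cohort: 600 patients, 12 variables, 10 days, ~7.5:1 imbalance;
# positive-class drift of 0.3/day on half the variables, starting on day 8
coh <- generate_cohort(synth_config(signal_onset_day = 8, seed = 11))
coh
#> <elstm_cohort>  N=600 patients, D=12 variables, T=10 days (58 positive, 542 negative)

train_idx <- setdiff(seq_len(600), seq(1, 600, by = 5))
fit <- elstm(cohort_subset(coh, train_idx),
             n_learners = 20, hidden_units = 16, epochs = 50, seed = 1)
fit
#> Ensemble of LSTM classifiers (eLSTM)
#>   20 base learners, 6 of 12 variables each, H=16 hidden units
#>   trained on 480 patients (gamma = 9.909)

test <- cohort_subset(coh, setdiff(seq_len(600), train_idx))
evaluation_report(predict(fit, test), cohort_labels(test))
#>   AUROC 0.8969 | AUPRC 0.6317  (n_pos=14, n_neg=106)
#>   at threshold 0.50: sens 0.6429, spec 0.9434, acc 0.9083, prec 0.6000, F1 0.6207

# day-by-day dynamic prediction: column k uses data through day k
daily <- predict_daily(fit, test)
round(apply(daily, 2, auroc, labels = cohort_labels(test)), 3)
#>  day1  day2  day3  day4  day5  day6  day7  day8  day9 day10
#> 0.598 0.530 0.459 0.480 0.374 0.562 0.571 0.722 0.876 0.897
```

The ensemble score is an estimated event probability: the report says the
model ranks a random positive above a random negative with probability 0.90
(AUROC), and at the default 0.5 cutoff it catches 64% of positives while
flagging ~6% of negatives — the trade-off produced by up-weighting positives
by γ ≈ 9.9 in training. The daily curve shows dynamic prediction doing
exactly what it should on this cohort: before the class signal begins on
day 8 the padded sequences carry no information and AUROC hovers at chance,
then discrimination climbs steeply as real post-onset measurements replace
carried-forward padding, reaching the static full-sequence value (0.897) on
the final day.

`run_experiment()` wraps the repeated-split protocol (stratified 90/10
splits, preprocessing refitted per fold, optional single-LSTM baseline and
P/m sweeps) and returns one row of metrics per repeat × model × setting;
`summary()` and `plot()` aggregate them. Model bundles written by
`save_elstm()` are plain JSON and reload bit-exactly with `load_elstm()`.
A command-line wrapper (`inst/cli/elstm`) exposes `synth`, `train`,
`predict`, `predict-daily` and `evaluate` subcommands over the same
functions.

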
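#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a daily-sampled ICU cohort:
#' `D` variables over `T` days per patient, a roughly 7.5:1
#' negative-to-positive class imbalance, temporally autocorrelated
#' trajectories whose trend differs by outcome class, and scattered missing
#' values. Each variable follows a stationary AR(1) process; for
#' positive-class patients the first `n_informative` variables additionally
#' drift upward by `effect_size` per day from `signal_onset_day` onward, so
#' class signal accumulates over the stay (late onsets exercise dynamic
#' prediction). It makes no attempt at clinical realism — no reference
#' ranges, units, or cross-variable correlation.
#'
#' @param n_patients Cohort size N.
#' @param D Number of variables (reference cohort: 50).
#' @param T Number of days (reference cohort: 10).
#' @param imbalance_ratio Target expected N_neg/N_pos (reference: ~7.5).
#' @param n_informative Variables carrying class signal (default `floor(D/2)`,
#'   always the first indices so subspace overlap with the signal is known).
#' @param effect_size Mean drift per day added to informative variables of
#'   positive patients, in noise-SD units (default 0.3).
#' @param ar_coefficient Lag-1 autocorrelation of every trajectory in [0, 1).
#' @param noise_sd Innovation standard deviation of the AR(1) process.
#' @param missing_rate Probability each entry is unobserved (MCAR).
#' @param signal_onset_day First day the drift applies (1 = whole stay).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 600, D = 12, T = 10,
                         imbalance_ratio = 7.5,
                         n_informative = max(1L, D %/% 2L),
                         effect_size = 0.3, ar_coefficient = 0.5,
                         noise_sd = 1, missing_rate = 0.1,
                         signal_onset_day = 1, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            ar_coefficient >= 0, ar_coefficient < 1,
            n_informative >= 1, n_informative <= D,
            signal_onset_day >= 1, signal_onset_day <= T,
            imbalance_ratio > 0)
  if (n_patients / (1 + imbalance_ratio) < 1 ||
      n_patients * imbalance_ratio / (1 + imbalance_ratio) < 1)
    stop("configuration yields an expected class count below 1")
  structure(list(n_patients = as.integer(n_patients), D = as.integer(D),
                 T = as.integer(T), imbalance_ratio = imbalance_ratio,
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, ar_coefficient = ar_coefficient,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 signal_onset_day = as.integer(signal_onset_day),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic clinical-style cohort
#'
#' Labels are drawn i.i.d. Bernoulli with positive probability
#' `1 / (1 + imbalance_ratio)`, so the expected negative-to-positive ratio
#' equals the target. Trajectories start from the stationary AR(1)
#' distribution (`sd = noise_sd / sqrt(1 - phi^2)`). The drift added to
#' informative variables of positive patients at day `t >= onset` is
#' `effect_size * (t - onset + 1)` — signal accumulates day by day. Entries
#' are masked missing independently at `missing_rate`; if a patient would
#' lose every entry, one is kept observed.
#'
#' @param config A [synth_config()].
#' @return An `elstm_cohort` with variables named `var01 ...`.
#' @examples
#' coh <- generate_cohort(synth_config(n_patients = 50, D = 4, T = 6, seed = 2))
#' coh
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients; d <- config$D; tt <- config$T
  phi <- config$ar_coefficient
  labels <- stats::rbinom(n, 1, 1 / (1 + config$imbalance_ratio))
  onset <- config$signal_onset_day
  drift <- pmax(seq_len(tt) - onset + 1, 0) * config$effect_size
  stat_sd <- config$noise_sd / sqrt(1 - phi^2)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    v <- matrix(0, d, tt)
    v[, 1] <- stats::rnorm(d, 0, stat_sd)
    if (tt > 1) for (t in 2:tt)
      v[, t] <- phi * v[, t - 1] + stats::rnorm(d, 0, config$noise_sd)
    if (labels[i] == 1)
      v[seq_len(config$n_informative), ] <-
        v[seq_len(config$n_informative), , drop = FALSE] +
        rep(drift, each = config$n_informative)
    obs <- matrix(stats::runif(d * tt) >= config$missing_rate, d, tt)
    if (!any(obs)) obs[1, 1] <- TRUE
    v[!obs] <- NA_real_
    patients[[i]] <- patient_series(sprintf("synth%05d", i), v, labels[i],
                                    observed = obs)
  }
  new_cohort(patients, sprintf("var%02d", seq_len(d)))
}

#' Deterministic hand-written miniature cohort
#'
#' Six patients, two variables, three days — small enough that imputation,
#' normalisation, class ratio and padding answers can be verified by hand.
#' Four negatives and two positives give gamma = 2. Patient `w2`'s first
#' variable has exactly one missing entry (track 1, NA, 3) whose
#' linear-interpolation fill is 2.
#'
#' @return An `elstm_cohort`.
#' @export
worked_fixture <- function() {
  mk <- function(id, v1, v2, label)
    patient_series(id, unname(rbind(v1, v2)), label)
  new_cohort(list(
    mk("w1", c(1, 2, 3),  c(0, 0, 0),  0),
    mk("w2", c(1, NA, 3), c(1, 1, 1),  0),
    mk("w3", c(2, 2, 2),  c(0, 1, 2),  0),
    mk("w4", c(3, 2, 1),  c(2, 1, 0),  0),
    mk("w5", c(4, 5, 6),  c(3, 3, 3),  1),
    mk("w6", c(5, 5, 5),  c(2, 3, 4),  1)),
    c("hr", "lactate"))
}
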
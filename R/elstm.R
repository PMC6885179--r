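#' @useDynLib elstm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# stable seed derivation: learner p's stream depends only on (master_seed, p),
# so adding learners never perturbs existing ones and training order is
# irrelevant. Exact integer arithmetic in doubles (< 2^53), result < 2^31.
mix_seed <- function(master_seed, k) {
  x <- (as.double(master_seed) %% 2147483647) * 1000003 +
    as.double(k) * 10007 + 12345
  as.integer(x %% 2147483629)
}

#' Ensemble configuration
#'
#' Reference-scale defaults: P = 200 base classifiers, each trained on a
#' bootstrap resample of the patients and a random half of the variables
#' (`subset_size = floor(D/2)`), for exactly 100 epochs without early
#' stopping.
#'
#' @param n_learners Number of base LSTM classifiers P.
#' @param subset_size Variables per base learner m; `NULL` means `floor(D/2)`.
#' @param train_settings A [train_settings()] object for the base learners
#'   (its `early_stop` is forced to `FALSE` and its per-learner seeds are
#'   derived from `master_seed`).
#' @param master_seed Integer seed for the whole ensemble.
#' @return A list of class `elstm_config`.
#' @export
elstm_config <- function(n_learners = 200, subset_size = NULL,
                         train_settings = elstm::train_settings(early_stop = FALSE),
                         master_seed = 1) {
  stopifnot(n_learners >= 1)
  train_settings$early_stop <- FALSE
  structure(list(n_learners = as.integer(n_learners),
                 subset_size = if (is.null(subset_size)) NULL else as.integer(subset_size),
                 train_settings = train_settings,
                 master_seed = as.integer(master_seed)),
            class = "elstm_config")
}

#' Generate bootstrap + random-subspace training subsets
#'
#' Each of the P subsets pairs `N` patient indices drawn i.i.d. uniformly with
#' replacement (standard bagging, resample size N) with a uniformly random
#' `m`-subset of the `D` variables drawn without replacement. Subset p's
#' randomness is derived deterministically from `(master_seed, p)`.
#'
#' @param N Number of training instances.
#' @param D Number of variables.
#' @param config An [elstm_config()].
#' @return List of P subset specs, each with 1-based `instance_indices`
#'   (length N, repeats expected) and sorted distinct `variable_indices`
#'   (length m).
#' @export
make_subsets <- function(N, D, config) {
  stopifnot(N >= 2)
  m <- if (is.null(config$subset_size)) max(1L, D %/% 2L) else config$subset_size
  if (m > D) stop("`subset_size` cannot exceed the number of variables")
  lapply(seq_len(config$n_learners), function(p) {
    set.seed(mix_seed(config$master_seed, p))
    list(instance_indices = sample.int(N, N, replace = TRUE),
         variable_indices = sort(sample.int(D, m, replace = FALSE)),
         seed = mix_seed(config$master_seed, p))
  })
}

#' Fit an ensemble of LSTM classifiers (eLSTM)
#'
#' Trains P base LSTM classifiers, each on a bootstrap resample of the
#' training patients restricted to a random subset of m variables, and
#' predicts by averaging their sigmoid scores. The positive class is weighted
#' by gamma = N_neg/N_pos (computed once from the full training cohort) in
#' every base learner's loss. Preprocessing — linear-interpolation imputation
#' and per-variable z-scoring — is fitted on the training cohort and stored in
#' the model so test-time preprocessing is identical.
#'
#' A bootstrap resample that happens to contain a single class is redrawn (up
#' to 100 attempts), since the weighted loss needs both classes.
#'
#' @param cohort A raw (unpreprocessed) `elstm_cohort` with both classes.
#' @param n_learners Number of base classifiers P (reference scale: 200).
#' @param subset_size Variables per learner m; default `floor(D/2)`.
#' @param hidden_units,dropout_rate,learning_rate,epochs,batch_size Training
#'   hyper-parameters for every base learner; see [train_settings()].
#' @param seed Master seed; the entire fit is reproducible from it and
#'   learners are mutually independent given it (training order never
#'   matters).
#' @param config Alternatively, a full [elstm_config()]; overrides the
#'   individual arguments.
#' @param verbose Print one line per trained learner?
#' @return An object of class `elstm` with components `learners` (each a
#'   `params` + `variable_indices` pair), `stats` (normalisation),
#'   `gamma`, `variable_names`, `config`, and the training-cohort `fitted`
#'   scores and `labels`.
#' @seealso [predict.elstm()], [predict_daily()], [lstm_baseline()]
#' @examples
#' \donttest{
#' coh <- generate_cohort(synth_config(n_patients = 80, D = 6, T = 5, seed = 1))
#' fit <- elstm(coh, n_learners = 3, hidden_units = 4, epochs = 5, seed = 1)
#' fit
#' predict(fit, coh)[1:5]
#' }
#' @export
elstm <- function(cohort, n_learners = 200, subset_size = NULL,
                  hidden_units = 64, dropout_rate = 0.5, learning_rate = 0.01,
                  epochs = 100, batch_size = 0, seed = 1, config = NULL,
                  verbose = FALSE) {
  cl <- match.call()
  if (is.null(config)) {
    config <- elstm_config(
      n_learners = n_learners, subset_size = subset_size,
      train_settings = train_settings(hidden_units = hidden_units,
                                      dropout_rate = dropout_rate,
                                      learning_rate = learning_rate,
                                      max_epochs = epochs,
                                      batch_size = batch_size,
                                      early_stop = FALSE),
      master_seed = seed)
  }
  labels <- cohort_labels(cohort)
  if (length(unique(labels)) < 2) stop("training cohort must contain both classes")
  gamma <- compute_class_ratio(cohort)

  prep <- preprocess_cohort(cohort)
  arr <- cohort_array(prep$cohort)
  N <- dim(arr)[1]; D <- dim(arr)[2]

  subsets <- make_subsets(N, D, config)
  learners <- lapply(seq_along(subsets), function(p) {
    sub <- subsets[[p]]
    idx <- sub$instance_indices
    # the weighted loss is undefined on a single-class resample: redraw
    attempt <- 0
    while (length(unique(labels[idx])) < 2 && attempt < 100) {
      attempt <- attempt + 1
      set.seed(mix_seed(sub$seed, 100000L + attempt))
      idx <- sample.int(N, N, replace = TRUE)
    }
    if (length(unique(labels[idx])) < 2)
      stop("could not draw a bootstrap sample containing both classes")
    st <- config$train_settings
    st$seed <- sub$seed
    x <- arr[idx, sub$variable_indices, , drop = FALSE]
    params <- train_lstm(x, labels[idx], gamma, st)
    if (verbose)
      message(sprintf("learner %3d/%d  seed=%d  m=%d  final loss=%.4f",
                      p, length(subsets), sub$seed,
                      length(sub$variable_indices),
                      utils::tail(attr(params, "train_loss"), 1)))
    list(params = params, variable_indices = sub$variable_indices,
         seed = sub$seed)
  })

  model <- structure(list(learners = learners, stats = prep$stats,
                          gamma = gamma,
                          variable_names = cohort$variable_names,
                          config = config, labels = labels, call = cl),
                     class = "elstm")
  model$fitted <- predict_on_array(model, arr)
  model
}

#' Single-LSTM baseline classifier
#'
#' The non-ensemble reference model: one LSTM trained on the full training
#' cohort with all variables, using a stratified validation split (10% by
#' default) to select the best epoch. Returned as a degenerate `elstm` object
#' (P = 1, m = D) so every downstream method applies unchanged.
#'
#' @param cohort A raw `elstm_cohort` with both classes.
#' @param hidden_units,dropout_rate,learning_rate,epochs,batch_size,seed As
#'   in [elstm()].
#' @param validation_fraction Held-out fraction for best-epoch selection.
#' @return An `elstm` object with a single learner.
#' @export
lstm_baseline <- function(cohort, hidden_units = 64, dropout_rate = 0.5,
                          learning_rate = 0.01, epochs = 100,
                          validation_fraction = 0.1, batch_size = 0, seed = 1) {
  cl <- match.call()
  labels <- cohort_labels(cohort)
  if (length(unique(labels)) < 2) stop("training cohort must contain both classes")
  gamma <- compute_class_ratio(cohort)
  prep <- preprocess_cohort(cohort)
  arr <- cohort_array(prep$cohort)
  st <- train_settings(hidden_units = hidden_units, dropout_rate = dropout_rate,
                       learning_rate = learning_rate, max_epochs = epochs,
                       validation_fraction = validation_fraction,
                       early_stop = TRUE, batch_size = batch_size, seed = seed)
  params <- train_lstm(arr, labels, gamma, st)
  config <- elstm_config(n_learners = 1, subset_size = dim(arr)[2],
                         train_settings = st, master_seed = seed)
  config$train_settings$early_stop <- TRUE  # record the mode actually used
  model <- structure(list(learners = list(list(params = params,
                                               variable_indices = seq_len(dim(arr)[2]),
                                               seed = st$seed)),
                          stats = prep$stats, gamma = gamma,
                          variable_names = cohort$variable_names,
                          config = config, labels = labels, call = cl),
                     class = "elstm")
  model$fitted <- predict_on_array(model, arr)
  model
}

# per-learner scores on a preprocessed n x D x T array -> n x P matrix
learner_scores_on_array <- function(model, arr) {
  vapply(model$learners, function(l) {
    forward_scores(l$params, arr[, l$variable_indices, , drop = FALSE])
  }, numeric(dim(arr)[1]))
}

predict_on_array <- function(model, arr, individual = FALSE) {
  sc <- learner_scores_on_array(model, arr)
  sc <- matrix(sc, nrow = dim(arr)[1])  # keep matrix shape for n = 1
  if (individual) sc else rowMeans(sc)
}

# preprocess new data with the model's stored stats and return the array view
model_preprocess <- function(model, newdata) {
  if (inherits(newdata, "patient_series"))
    newdata <- new_cohort(list(newdata), model$variable_names)
  if (!inherits(newdata, "elstm_cohort"))
    stop("`newdata` must be an elstm_cohort or a patient_series")
  if (length(newdata$variable_names) != length(model$variable_names))
    stop("`newdata` has a different variable count than the fitted model")
  cohort_array(preprocess_cohort(newdata, stats = model$stats)$cohort)
}

#' Predict mortality-style risk scores from a fitted ensemble
#'
#' Applies the stored preprocessing to `newdata`, scores it with every base
#' classifier on that learner's variable subset, and averages:
#' `Y = (1/P) sum_p y_p`. The averaged score always lies inside the range of
#' the individual scores and is invariant to learner order.
#'
#' @param object A fitted [elstm()] model.
#' @param newdata An `elstm_cohort` or a single `patient_series` (raw;
#'   preprocessing is applied internally).
#' @param type `"response"` for scores in [0, 1].
#' @param individual Return the `n x P` matrix of per-learner scores instead
#'   of their average?
#' @param ... Ignored.
#' @return Numeric vector of scores (or a matrix when `individual = TRUE`).
#' @export
predict.elstm <- function(object, newdata, type = "response",
                          individual = FALSE, ...) {
  type <- match.arg(type, "response")
  arr <- model_preprocess(object, newdata)
  out <- predict_on_array(object, arr, individual = individual)
  if (!individual && inherits(newdata, "patient_series")) out <- unname(out)
  out
}

#' @export
print.elstm <- function(x, ...) {
  m <- length(x$learners[[1]]$variable_indices)
  cat("Ensemble of LSTM classifiers (eLSTM)\n")
  cat(sprintf("  %d base learner%s, %d of %d variables each, H=%d hidden units\n",
              length(x$learners), if (length(x$learners) > 1) "s" else "",
              m, length(x$variable_names),
              x$config$train_settings$hidden_units))
  cat(sprintf("  trained on %d patients (gamma = %.3f)\n",
              length(x$labels), x$gamma))
  invisible(x)
}

#' @export
summary.elstm <- function(object, threshold = 0.5, ...) {
  rep <- evaluation_report(object$fitted, object$labels, threshold = threshold)
  out <- list(model = object, train_report = rep,
              epochs = vapply(object$learners,
                              function(l) attr(l$params, "epochs_run"),
                              numeric(1)))
  class(out) <- "summary.elstm"
  out
}

#' @export
print.summary.elstm <- function(x, ...) {
  print(x$model)
  cat("\nApparent (training-cohort) performance:\n")
  print(x$train_report)
  invisible(x)
}

#' @export
coef.elstm <- function(object, ...) {
  lapply(object$learners, function(l)
    list(variable_indices = l$variable_indices, params = unclass(l$params)))
}

#' @export
fitted.elstm <- function(object, ...) object$fitted

#' @export
residuals.elstm <- function(object, ...) object$labels - object$fitted

#' Simulate outcome labels from fitted risk scores
#'
#' Draws Bernoulli labels at the model's averaged scores for the supplied
#' cohort (training scores when `newdata` is missing).
#'
#' @param object A fitted `elstm` model.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional integer seed.
#' @param newdata Optional cohort to score first.
#' @param ... Ignored.
#' @return A data.frame with `nsim` columns of 0/1 labels.
#' @export
simulate.elstm <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(newdata)) object$fitted else predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot per-learner score spread for a cohort
#'
#' Shows each patient's averaged ensemble score (points, coloured by true
#' label when available) over the range of its individual base-learner
#' scores (segments) — a direct view of ensemble agreement.
#'
#' @param x A fitted `elstm` model.
#' @param newdata Cohort to score; defaults to refusing silently to the
#'   training fit (scores only, no ranges).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.elstm <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    scores <- sort(x$fitted)
    graphics::plot(scores, ylim = c(0, 1), xlab = "patient (sorted)",
                   ylab = "ensemble score", pch = 16, ...)
    return(invisible(x))
  }
  sc <- predict(x, newdata, individual = TRUE)
  avg <- rowMeans(sc)
  o <- order(avg)
  lab <- cohort_labels(newdata)
  graphics::plot(avg[o], ylim = c(0, 1), xlab = "patient (sorted by score)",
                 ylab = "score", pch = 16,
                 col = ifelse(lab[o] == 1, "firebrick", "grey40"), ...)
  graphics::segments(seq_along(o), apply(sc, 1, min)[o],
                     seq_along(o), apply(sc, 1, max)[o],
                     col = "grey70")
  graphics::points(avg[o], pch = 16,
                   col = ifelse(lab[o] == 1, "firebrick", "grey40"))
  invisible(x)
}
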
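#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney rank statistic: the probability
#' that a uniformly drawn positive scores above a uniformly drawn negative,
#' with ties counted half. Equal to the trapezoidal area under the exact ROC
#' curve evaluated at every distinct score, and invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length; both classes required.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes are required to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Uses the step-wise average-precision rule: thresholds sweep the distinct
#' scores from high to low and each recall increment is weighted by the
#' precision at that threshold. (Trapezoidal interpolation in PR space is
#' optimistic and deliberately avoided.) The chance level equals the
#' positive-class prevalence.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1); at least one positive required.
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("at least one positive is required to compute AUPRC")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Predicted positive iff `score >= threshold`. When no instance is predicted
#' positive, precision and F1 are reported as 0 with the `undefined_precision`
#' flag set.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1); both classes required.
#' @param threshold Decision cutoff (default 0.5).
#' @return A list with `sensitivity` (= recall), `specificity`, `accuracy`,
#'   `precision`, `f1`, the confusion counts and the threshold.
#' @export
thresholded_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes are required")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  undefined <- (tp + fp) == 0
  prec <- if (undefined) 0 else tp / (tp + fp)
  f1 <- if (prec > 0 && sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       precision = prec, f1 = f1, threshold = threshold,
       tp = tp, fp = fp, tn = tn, fn = fn,
       undefined_precision = undefined)
}

#' Full evaluation report for a score vector
#'
#' Bundles the threshold-free metrics (AUROC, AUPRC) with the thresholded
#' ones at a single cutoff.
#'
#' @inheritParams thresholded_metrics
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(scores, labels, threshold = 0.5) {
  tm <- thresholded_metrics(scores, labels, threshold)
  structure(c(list(auroc = auroc(scores, labels),
                   auprc = auprc(scores, labels)),
              tm,
              list(n_pos = sum(labels == 1), n_neg = sum(labels == 0))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("  AUROC %.4f | AUPRC %.4f  (n_pos=%d, n_neg=%d)\n",
              x$auroc, x$auprc, x$n_pos, x$n_neg))
  cat(sprintf("  at threshold %.2f: sens %.4f, spec %.4f, acc %.4f, prec %.4f, F1 %.4f\n",
              x$threshold, x$sensitivity, x$specificity, x$accuracy,
              x$precision, x$f1))
  invisible(x)
}

# stratified train/test split: returns test indices
stratified_split <- function(labels, test_fraction, seed) {
  set.seed(as.integer(seed))
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- min(length(idx) - 1L, max(1L, round(test_fraction * length(idx))))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

report_row <- function(.report, ...) {
  data.frame(..., auroc = .report$auroc, auprc = .report$auprc,
             sensitivity = .report$sensitivity, specificity = .report$specificity,
             accuracy = .report$accuracy, precision = .report$precision, f1 = .report$f1)
}

#' Repeated train/test-split experiment harness
#'
#' Runs `n_repeats` independent stratified splits. In each repeat an eLSTM
#' with `max(p_grid)` base learners is fitted on the training fold (and,
#' optionally, the single-LSTM baseline); test-fold metrics are reported for
#' every ensemble size in `p_grid` by averaging the score of the first P
#' learners — learners are independent given their seeds, so the first P of a
#' larger ensemble are exactly the ensemble of size P. An optional `m_grid`
#' refits the ensemble at each variable-subset size. With `daily = TRUE`,
#' per-day AUROC/AUPRC from [predict_daily()] are appended (day `NA` rows are
#' the static, full-sequence evaluation).
#'
#' Reference scale is 50 repeats of 90/10 splits; desk-scale studies use
#' fewer repeats and smaller ensembles.
#'
#' @param cohort A raw `elstm_cohort`.
#' @param n_repeats Number of repeated splits.
#' @param test_fraction Held-out fraction per split.
#' @param p_grid Ensemble sizes to evaluate (one fit per repeat at `max(p_grid)`).
#' @param m_grid Optional variable-subset sizes (one extra fit per value).
#' @param baseline Also fit the single-LSTM baseline per repeat?
#' @param daily Also evaluate day-by-day dynamic prediction?
#' @param threshold Decision cutoff for the thresholded metrics.
#' @param hidden_units,dropout_rate,learning_rate,epochs Hyper-parameters
#'   passed to [elstm()] and [lstm_baseline()].
#' @param seed Master seed; repeat r derives its split and model seeds from it.
#' @param verbose Print a line per repeat?
#' @return A data.frame with one row per (repeat, model, P, m, day)
#'   combination and columns for every metric, plus the seeds used.
#' @export
run_experiment <- function(cohort, n_repeats = 10, test_fraction = 0.1,
                           p_grid = 20, m_grid = NULL, baseline = TRUE,
                           daily = FALSE, threshold = 0.5,
                           hidden_units = 16, dropout_rate = 0.5,
                           learning_rate = 0.01, epochs = 50,
                           seed = 1, verbose = FALSE) {
  labels <- cohort_labels(cohort)
  D <- length(cohort$variable_names)
  p_grid <- sort(unique(as.integer(p_grid)))
  rows <- list()
  for (r in seq_len(n_repeats)) {
    split_seed <- mix_seed(seed, 7000L + r)
    test_idx <- stratified_split(labels, test_fraction, split_seed)
    train <- cohort_subset(cohort, setdiff(seq_along(labels), test_idx))
    test <- cohort_subset(cohort, test_idx)
    test_lab <- cohort_labels(test)

    fit <- elstm(train, n_learners = max(p_grid),
                 hidden_units = hidden_units, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, epochs = epochs,
                 seed = mix_seed(seed, r))
    arr_test <- model_preprocess(fit, test)
    sc <- predict_on_array(fit, arr_test, individual = TRUE)
    for (P in p_grid) {
      scores <- rowMeans(sc[, seq_len(P), drop = FALSE])
      rows[[length(rows) + 1]] <- report_row(
        evaluation_report(scores, test_lab, threshold),
        rep = r, model = "elstm", P = P,
        m = length(fit$learners[[1]]$variable_indices), day = NA_integer_,
        split_seed = split_seed)
    }
    if (daily) {
      dsc <- predict_daily(fit, test)
      for (k in seq_len(ncol(dsc))) {
        rows[[length(rows) + 1]] <- report_row(
          evaluation_report(dsc[, k], test_lab, threshold),
          rep = r, model = "elstm", P = max(p_grid),
          m = length(fit$learners[[1]]$variable_indices), day = k,
          split_seed = split_seed)
      }
    }
    if (!is.null(m_grid)) {
      for (mm in sort(unique(as.integer(m_grid)))) {
        fit_m <- elstm(train, n_learners = max(p_grid), subset_size = mm,
                       hidden_units = hidden_units,
                       dropout_rate = dropout_rate,
                       learning_rate = learning_rate, epochs = epochs,
                       seed = mix_seed(seed, 5000L + r))
        rows[[length(rows) + 1]] <- report_row(
          evaluation_report(predict(fit_m, test), test_lab, threshold),
          rep = r, model = "elstm_m", P = max(p_grid), m = mm,
          day = NA_integer_, split_seed = split_seed)
      }
    }
    if (baseline) {
      base_fit <- lstm_baseline(train, hidden_units = hidden_units,
                                dropout_rate = dropout_rate,
                                learning_rate = learning_rate, epochs = epochs,
                                seed = mix_seed(seed, 3000L + r))
      base_scores <- predict(base_fit, test)
      rows[[length(rows) + 1]] <- report_row(
        evaluation_report(base_scores, test_lab, threshold),
        rep = r, model = "lstm", P = 1L, m = D, day = NA_integer_,
        split_seed = split_seed)
      if (daily) {
        dscb <- predict_daily(base_fit, test)
        for (k in seq_len(ncol(dscb))) {
          rows[[length(rows) + 1]] <- report_row(
            evaluation_report(dscb[, k], test_lab, threshold),
            rep = r, model = "lstm", P = 1L, m = D, day = k,
            split_seed = split_seed)
        }
      }
    }
    if (verbose) message(sprintf("repeat %d/%d done", r, n_repeats))
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("elstm_experiment", class(out))
  out
}

#' Summarise an experiment table
#'
#' Mean and standard deviation of each metric over repeats, grouped by
#' (model, P, m, day).
#'
#' @param object A result table from [run_experiment()].
#' @param ... Ignored.
#' @return A data.frame of group means and standard deviations.
#' @export
summary.elstm_experiment <- function(object, ...) {
  df <- as.data.frame(object)
  key <- interaction(df$model, df$P, df$m, ifelse(is.na(df$day), 0L, df$day),
                     drop = TRUE)
  metrics <- c("auroc", "auprc", "sensitivity", "specificity", "accuracy",
               "precision", "f1")
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    cbind(g[1, c("model", "P", "m", "day")],
          as.data.frame(c(setNames(lapply(metrics, function(v) mean(g[[v]])),
                                   metrics),
                          setNames(lapply(metrics, function(v) stats::sd(g[[v]])),
                                   paste0(metrics, "_sd"))),
                        optional = TRUE),
          n = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$model, out$m, out$P, out$day, na.last = FALSE), ]
}

#' Plot experiment summaries
#'
#' Line charts of mean AUROC (with one-standard-deviation whiskers) against
#' the study axis: `"day"` for dynamic-prediction curves, `"P"` for the
#' ensemble-size sweep, `"m"` for the subset-size sweep.
#'
#' @param x A result table from [run_experiment()].
#' @param against One of `"day"`, `"P"`, `"m"`.
#' @param metric Metric column to plot (default `"auroc"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.elstm_experiment <- function(x, against = c("day", "P", "m"),
                                  metric = "auroc", ...) {
  against <- match.arg(against)
  s <- summary(x)
  s <- if (against == "day") s[!is.na(s$day), ] else s[is.na(s$day), ]
  if (!nrow(s)) stop("no rows for this axis in the experiment table")
  graphics::plot(range(s[[against]]), range(c(s[[metric]] - s[[paste0(metric, "_sd")]],
                                              s[[metric]] + s[[paste0(metric, "_sd")]])),
                 type = "n", xlab = against, ylab = paste("mean", metric), ...)
  models <- unique(s$model)
  for (i in seq_along(models)) {
    g <- s[s$model == models[i], ]
    g <- g[order(g[[against]]), ]
    graphics::lines(g[[against]], g[[metric]], col = i, type = "b", pch = 16)
    graphics::arrows(g[[against]], g[[metric]] - g[[paste0(metric, "_sd")]],
                     g[[against]], g[[metric]] + g[[paste0(metric, "_sd")]],
                     angle = 90, code = 3, length = 0.03, col = i)
  }
  graphics::legend("bottomright", legend = models, col = seq_along(models),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
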
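#' Construct a single patient's time series
#'
#' A patient series holds a `D x T` matrix of daily clinical measurements
#' (variables in rows, days in columns), the matching observed-mask, and the
#' binary outcome label (0 = survival, 1 = death). Days are 1-based
#' (\code{D1 ... DT}) throughout the R interface.
#'
#' @param id Patient identifier (coerced to character).
#' @param values Numeric `D x T` matrix; `NA` where no measurement exists.
#' @param label Binary outcome, 0 or 1.
#' @param observed Logical `D x T` matrix; defaults to `!is.na(values)`.
#' @param observed_through Last day (1..T) with any recorded data; computed
#'   from `observed` when missing.
#' @return An object of class `patient_series`.
#' @examples
#' ps <- patient_series("p1", matrix(c(1, NA, 3, 5, 5, NA), nrow = 2,
#'                                   byrow = TRUE), label = 1)
#' ps$observed_through
#' @export
patient_series <- function(id, values, label,
                           observed = !is.na(values),
                           observed_through = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  observed <- as.matrix(observed)
  if (!identical(dim(values), dim(observed)))
    stop("`values` and `observed` must have identical dimensions")
  if (any(observed & !is.finite(values)))
    stop("observed entries must be finite")
  if (!(length(label) == 1L && label %in% c(0, 1)))
    stop("`label` must be 0 or 1")
  if (is.null(observed_through)) {
    days_with_data <- which(colSums(observed) > 0)
    observed_through <- if (length(days_with_data)) max(days_with_data) else 1L
  }
  if (observed_through < 1L || observed_through > ncol(values))
    stop("`observed_through` must lie in [1, T]")
  structure(list(id = as.character(id), values = values, observed = observed,
                 label = as.integer(label),
                 observed_through = as.integer(observed_through)),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series %s>  D=%d variables x T=%d days, label=%d, observed through day %d\n",
              x$id, nrow(x$values), ncol(x$values), x$label, x$observed_through))
  invisible(x)
}

#' Construct a cohort of patient series
#'
#' All patients must share the same number of variables `D` and days `T`.
#' The negative-to-positive class ratio gamma, used to weight the positive
#' class in the training loss, is always recomputed from the current members
#' via [compute_class_ratio()].
#'
#' @param patients List of [patient_series()] objects.
#' @param variable_names Character vector of length `D` naming the variables.
#' @return An object of class `elstm_cohort`.
#' @export
new_cohort <- function(patients, variable_names) {
  if (!length(patients)) stop("cohort must contain at least one patient")
  dims <- vapply(patients, function(p) dim(p$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all patients must share the same D and T")
  if (length(variable_names) != dims[1, 1])
    stop("`variable_names` must have length D")
  structure(list(patients = patients,
                 variable_names = as.character(variable_names)),
            class = "elstm_cohort")
}

#' @export
print.elstm_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<elstm_cohort>  N=%d patients, D=%d variables, T=%d days (%d positive, %d negative)\n",
              length(x$patients), length(x$variable_names),
              ncol(x$patients[[1]]$values), sum(lab == 1), sum(lab == 0)))
  invisible(x)
}

#' @export
length.elstm_cohort <- function(x) length(x$patients)

#' Outcome labels of a cohort
#' @param cohort An `elstm_cohort`.
#' @return Integer vector of 0/1 labels, one per patient.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$patients, function(p) p$label, integer(1))
}

#' Negative-to-positive class ratio
#'
#' Returns gamma = N_neg / N_pos, the weight applied to positive instances in
#' the weighted cross-entropy loss. In the motivating 28-day ICU mortality
#' cohort this ratio is about 7.5.
#'
#' @param cohort An `elstm_cohort`.
#' @return A single positive number.
#' @export
compute_class_ratio <- function(cohort) {
  lab <- cohort_labels(cohort)
  n_pos <- sum(lab == 1)
  if (n_pos == 0) stop("cohort has no positive instances; class ratio undefined")
  sum(lab == 0) / n_pos
}

#' Subset a cohort by patient index
#' @param cohort An `elstm_cohort`.
#' @param idx Integer indices (repeats allowed, as in bootstrap samples).
#' @return A new `elstm_cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  new_cohort(cohort$patients[idx], cohort$variable_names)
}

# n x D x T array view of a cohort (row-major over patients); used by the
# batched C++ forward/backward paths
cohort_array <- function(cohort) {
  n <- length(cohort$patients)
  d <- length(cohort$variable_names)
  tt <- ncol(cohort$patients[[1]]$values)
  arr <- array(NA_real_, dim = c(n, d, tt))
  for (i in seq_len(n)) arr[i, , ] <- cohort$patients[[i]]$values
  arr
}

#' Fill missing entries of one series by linear interpolation in time
#'
#' Internal gaps in each variable's daily track are filled on the straight
#' line between the nearest observed neighbours; leading/trailing gaps take
#' the first/last observed value (constant extension — interpolation needs
#' two anchors). A variable with no observations at all can only be filled if
#' `all_missing_fill` supplies a value for it; cohort-level preprocessing
#' passes the training-set variable means here, which become 0 after
#' normalisation.
#'
#' @param series A [patient_series()].
#' @param all_missing_fill Optional numeric vector of length `D` used for
#'   variables with zero observations.
#' @return The imputed `patient_series` with `observed` all `TRUE`; observed
#'   values are never altered.
#' @examples
#' s <- patient_series("a", matrix(c(1, NA, 3), 1), label = 0)
#' impute_linear(s)$values  # 1 2 3
#' @export
impute_linear <- function(series, all_missing_fill = NULL) {
  v <- series$values
  obs <- series$observed
  tt <- ncol(v)
  if (!any(obs)) stop("series has no observed data at all")
  for (d in seq_len(nrow(v))) {
    days <- which(obs[d, ])
    if (length(days) == tt) next
    if (length(days) == 0L) {
      if (is.null(all_missing_fill) || !is.finite(all_missing_fill[d]))
        stop(sprintf("variable %d has no observations; supply `all_missing_fill`", d))
      v[d, ] <- all_missing_fill[d]
    } else if (length(days) == 1L) {
      v[d, ] <- v[d, days]
    } else {
      v[d, ] <- stats::approx(days, v[d, days], xout = seq_len(tt),
                              method = "linear", rule = 2)$y
    }
  }
  patient_series(series$id, v, series$label,
                 observed = matrix(TRUE, nrow(v), tt),
                 observed_through = series$observed_through)
}

#' Fit per-variable normalisation statistics on a training cohort
#'
#' Means and standard deviations are pooled over all patients and all days of
#' the (already imputed) training cohort, one pair per variable. The sample
#' standard deviation (denominator n-1) is used. Entries still missing (a
#' variable never observed for some patient) are ignored.
#'
#' @param train An imputed `elstm_cohort`.
#' @return An object of class `norm_stats` with fields `mean` and `std`.
#' @export
fit_normalization <- function(train) {
  arr <- cohort_array(train)
  d <- dim(arr)[2]
  mu <- numeric(d); sd_ <- numeric(d)
  for (j in seq_len(d)) {
    x <- as.vector(arr[, j, ])
    x <- x[is.finite(x)]
    if (!length(x)) stop(sprintf("variable %d has no data in the training cohort", j))
    mu[j] <- mean(x)
    sd_[j] <- if (length(x) > 1) stats::sd(x) else 0
  }
  structure(list(mean = mu, std = sd_, variable_names = train$variable_names),
            class = "norm_stats")
}

#' Z-score one series with fitted statistics
#'
#' Each entry becomes `(x - mean[d]) / max(std[d], 1e-8)`; the floor keeps
#' zero-variance variables defined (they map to 0).
#'
#' @param series An imputed [patient_series()].
#' @param stats A `norm_stats` object from [fit_normalization()].
#' @return The normalised `patient_series`.
#' @export
apply_normalization <- function(series, stats) {
  if (nrow(series$values) != length(stats$mean))
    stop("variable count mismatch between series and normalisation stats")
  std <- pmax(stats$std, 1e-8)
  v <- (series$values - stats$mean) / std  # mean/std recycle down columns: rows are variables
  patient_series(series$id, v, series$label, observed = series$observed,
                 observed_through = series$observed_through)
}

#' Impute and normalise a cohort
#'
#' The full preprocessing pipeline: impute each patient by linear
#' interpolation, fit normalisation statistics on the imputed data (training
#' mode) or reuse supplied statistics (test mode), fill variables a patient
#' never had observed with the training mean, and z-score everything.
#' Statistics must come from training data only, so pass `stats` when
#' preprocessing a test set.
#'
#' @param cohort An `elstm_cohort`.
#' @param stats Optional `norm_stats`; fitted on `cohort` when `NULL`.
#' @return List with the preprocessed `cohort` and the `stats` used.
#' @export
preprocess_cohort <- function(cohort, stats = NULL) {
  # first pass: fill what each patient's own data supports
  partial <- lapply(cohort$patients, function(p) {
    v <- p$values
    obs <- p$observed
    if (!any(obs)) stop(sprintf("patient %s has no observed data", p$id))
    for (d in seq_len(nrow(v))) {
      days <- which(obs[d, ])
      if (length(days) == ncol(v) || length(days) == 0L) next
      v[d, ] <- if (length(days) == 1L) v[d, days] else
        stats::approx(days, v[d, days], xout = seq_len(ncol(v)),
                      method = "linear", rule = 2)$y
    }
    v[!is.finite(v)] <- NA_real_
    patient_series(p$id, v, p$label, observed = !is.na(v),
                   observed_through = p$observed_through)
  })
  partial <- new_cohort(partial, cohort$variable_names)
  if (is.null(stats)) stats <- fit_normalization(partial)
  done <- lapply(partial$patients, function(p) {
    p <- impute_linear(p, all_missing_fill = stats$mean)
    apply_normalization(p, stats)
  })
  list(cohort = new_cohort(done, cohort$variable_names), stats = stats)
}
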
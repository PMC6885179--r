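#' Pad a series to full length with the latest available data
#'
#' Last-observation-carried-forward padding for dynamic prediction: days
#' `1..k` are kept as-is and every later day copies the day-`k` value of each
#' variable, yielding a complete `D x T` sequence a full-sequence model can
#' score. Padding operates on imputed values.
#'
#' @param series An imputed [patient_series()].
#' @param k Cutoff day in `[1, T]`: the last day whose data may be used.
#' @return A `patient_series` with `observed_through = T`.
#' @examples
#' s <- patient_series("a", matrix(1:5, 1), label = 0)
#' pad_locf(s, 3)$values  # 1 2 3 3 3
#' @export
pad_locf <- function(series, k) {
  tt <- ncol(series$values)
  if (k < 1 || k > tt) stop("`k` must lie in [1, T]")
  v <- series$values
  if (k < tt) v[, (k + 1):tt] <- v[, k]
  patient_series(series$id, v, series$label,
                 observed = matrix(TRUE, nrow(v), tt),
                 observed_through = tt)
}

#' Day-by-day dynamic risk prediction
#'
#' Emulates bedside use of a full-sequence model: for every day `k`, the
#' series is truncated to what was observable through day `k`, padded forward
#' by [pad_locf()], and scored with the same trained ensemble — no per-day
#' retraining. Scores typically sharpen as real data replaces padding.
#'
#' @param model A fitted [elstm()] model.
#' @param newdata An `elstm_cohort` or single `patient_series` (raw).
#' @return An `n x T` matrix of scores (a length-`T` vector for a single
#'   series); column `k` uses data through day `k`, so column `T` equals the
#'   static [predict.elstm()] scores.
#' @export
predict_daily <- function(model, newdata) {
  single <- inherits(newdata, "patient_series")
  arr <- model_preprocess(model, newdata)
  tt <- dim(arr)[3]
  out <- matrix(NA_real_, dim(arr)[1], tt,
                dimnames = list(NULL, paste0("day", seq_len(tt))))
  for (k in seq_len(tt)) {
    padded <- arr
    if (k < tt) for (j in (k + 1):tt) padded[, , j] <- padded[, , k]
    out[, k] <- predict_on_array(model, padded)
  }
  if (single) out[1, ] else out
}
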
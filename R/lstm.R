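#' Glorot-uniform initialisation of LSTM parameters
#'
#' Each gate weight matrix maps the concatenation `[h_{t-1}, x_t]` (length
#' `H + m`) to `H` pre-activations and is drawn uniformly on
#' `+/- sqrt(6 / (fan_in + fan_out))`; biases start at zero. The read-out
#' layer maps `h_T` to a single logit. Deterministic given `seed`.
#'
#' @param H Hidden size (number of LSTM units).
#' @param m Input dimensionality (number of variables seen by this learner).
#' @param seed Integer seed.
#' @return An object of class `lstm_params` with gate matrices `w_f`, `w_i`,
#'   `w_o`, `w_c` (each `H x (H+m)`), bias vectors `b_f`, `b_i`, `b_o`, `b_c`,
#'   read-out weights `w_ho` (length `H`) and bias `b_ho`.
#' @export
init_lstm_params <- function(H, m, seed) {
  stopifnot(H >= 1, m >= 1)
  set.seed(as.integer(seed))
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- list(
    w_f = glorot(H, H + m, H + m, H),
    w_i = glorot(H, H + m, H + m, H),
    w_o = glorot(H, H + m, H + m, H),
    w_c = glorot(H, H + m, H + m, H),
    b_f = numeric(H), b_i = numeric(H), b_o = numeric(H), b_c = numeric(H),
    w_ho = as.numeric(glorot(H, 1, H, 1)),
    b_ho = 0,
    H = as.integer(H), m = as.integer(m))
  class(p) <- "lstm_params"
  p
}

#' @export
print.lstm_params <- function(x, ...) {
  cat(sprintf("<lstm_params>  H=%d hidden units, m=%d inputs (%d parameters)\n",
              x$H, x$m, 4 * x$H * (x$H + x$m) + 4 * x$H + x$H + 1))
  invisible(x)
}

# packed (single weight matrix) layout used by the C++ core; column blocks
# are [forget | input | output | candidate]
pack_params <- function(p) {
  list(W = t(rbind(p$w_f, p$w_i, p$w_o, p$w_c)),
       b = c(p$b_f, p$b_i, p$b_o, p$b_c),
       w_ho = p$w_ho, b_ho = p$b_ho, H = p$H, m = p$m)
}

unpack_params <- function(pk) {
  H <- pk$H
  Wt <- t(pk$W)  # 4H x (H+m), row blocks f,i,o,c
  blk <- function(k) Wt[((k - 1) * H + 1):(k * H), , drop = FALSE]
  bblk <- function(k) pk$b[((k - 1) * H + 1):(k * H)]
  structure(list(w_f = blk(1), w_i = blk(2), w_o = blk(3), w_c = blk(4),
                 b_f = bblk(1), b_i = bblk(2), b_o = bblk(3), b_c = bblk(4),
                 w_ho = as.numeric(pk$w_ho), b_ho = as.numeric(pk$b_ho),
                 H = as.integer(H), m = as.integer(pk$m)),
            class = "lstm_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' One LSTM time step
#'
#' The gated recurrence: with `z = [h_prev, x_t]`,
#' \deqn{f = \sigma(w_f z + b_f),\; i = \sigma(w_i z + b_i),\;
#'       o = \sigma(w_o z + b_o),}
#' \deqn{C = f * C_{prev} + i * \tanh(w_c z + b_c), \qquad h = o * \tanh(C),}
#' where `*` is the elementwise product. This plain-R path is the reference
#' definition of the recurrence; batch training uses an equivalent compiled
#' implementation.
#'
#' @param params An `lstm_params` object.
#' @param x_t Numeric input vector of length `m`.
#' @param prev List with hidden state `h` and cell memory `C` (each length `H`);
#'   defaults to the zero initial state.
#' @return List with the new `h` and `C`.
#' @export
lstm_step <- function(params, x_t, prev = NULL) {
  if (is.null(prev)) prev <- list(h = numeric(params$H), C = numeric(params$H))
  if (!all(is.finite(x_t))) stop("non-finite input to lstm_step")
  z <- c(prev$h, x_t)
  f <- sigmoid(drop(params$w_f %*% z) + params$b_f)
  i <- sigmoid(drop(params$w_i %*% z) + params$b_i)
  o <- sigmoid(drop(params$w_o %*% z) + params$b_o)
  g <- tanh(drop(params$w_c %*% z) + params$b_c)
  C <- f * prev$C + i * g
  list(h = o * tanh(C), C = C)
}

#' Score one full sequence with a single LSTM
#'
#' Iterates [lstm_step()] from the zero initial state over columns of `V`
#' (one per day) and applies the sigmoid read-out to the final hidden state:
#' `y = sigma(w_ho . h_T + b_ho)`. Dropout is never active at inference.
#'
#' @param params An `lstm_params` object.
#' @param V Numeric `m x T` matrix, fully imputed and normalised.
#' @return A score in (0, 1).
#' @export
lstm_forward <- function(params, V) {
  V <- as.matrix(V)
  if (ncol(V) == 0) stop("sequence has no time steps")
  if (nrow(V) != params$m) stop("input has wrong variable count for these parameters")
  st <- list(h = numeric(params$H), C = numeric(params$H))
  for (t in seq_len(ncol(V))) st <- lstm_step(params, V[, t], st)
  as.numeric(sigmoid(sum(params$w_ho * st$h) + params$b_ho))
}

#' Class-ratio weighted binary cross-entropy
#'
#' Positive instances are weighted by gamma (the negative-to-positive ratio of
#' the training cohort) and negative ones by 1:
#' `-gamma * log(score)` for label 1, `-log(1 - score)` for label 0.
#' Scores are clipped to `[1e-7, 1 - 1e-7]` so the loss stays finite. The
#' batch loss is the mean of the returned per-instance values.
#'
#' @param score Predicted scores in (0, 1); vectorised.
#' @param label Binary labels, same length.
#' @param gamma Positive-class weight, > 0.
#' @return Per-instance non-negative losses.
#' @export
weighted_bce <- function(score, label, gamma) {
  if (gamma <= 0) stop("`gamma` must be positive")
  s <- pmin(pmax(score, 1e-7), 1 - 1e-7)
  -(gamma * label * log(s) + (1 - label) * log(1 - s))
}

#' Training settings for one LSTM classifier
#'
#' Defaults follow the reference recipe for this model family: 64 hidden
#' units, input-layer dropout 0.5, Adam at learning rate 0.01, at most 100
#' epochs. `early_stop = TRUE` (the single-LSTM mode) holds out
#' `validation_fraction` of the training instances, stratified by label, and
#' returns the parameters from the epoch with the lowest validation loss;
#' ensemble members instead train for exactly `max_epochs` epochs
#' (`early_stop = FALSE`), the bias-control convention for bagged learners.
#' `batch_size = 0` means full-batch gradient steps.
#'
#' @param hidden_units Hidden size `H`.
#' @param dropout_rate Input-layer dropout probability in [0, 1).
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum (or, without early stopping, exact) epoch count.
#' @param validation_fraction Fraction held out when `early_stop`.
#' @param early_stop Use validation-based best-epoch selection?
#' @param batch_size Mini-batch size; 0 for full batch.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @param seed Integer seed controlling initialisation, dropout and shuffling.
#' @return A list of class `train_settings`.
#' @export
train_settings <- function(hidden_units = 64, dropout_rate = 0.5,
                           learning_rate = 0.01, max_epochs = 100,
                           validation_fraction = 0.1, early_stop = FALSE,
                           batch_size = 0, beta1 = 0.9, beta2 = 0.999,
                           adam_eps = 1e-8, seed = 1) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1,
            hidden_units >= 1, max_epochs >= 1, learning_rate > 0)
  if (early_stop && !(validation_fraction > 0 && validation_fraction < 1))
    stop("`validation_fraction` must be in (0, 1) when early stopping")
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 early_stop = isTRUE(early_stop),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "train_settings")
}

# stratified validation indices (1-based); at least one instance per class
# stays in training
stratified_validation_split <- function(labels, fraction, seed) {
  set.seed(as.integer(seed))
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- min(length(idx) - 1L, max(1L, floor(fraction * length(idx))))
    if (n_val > 0 && length(idx) > 1) val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train one LSTM classifier by gradient descent
#'
#' Minimises the mean gamma-weighted cross-entropy with Adam. Input-layer
#' dropout (mask resampled independently at every time step) is active during
#' training only. Fully reproducible from `settings$seed`.
#'
#' @param x Numeric array `n x m x T` of preprocessed sequences (patients x
#'   variables x days).
#' @param y Binary labels of length `n`; both classes must be present.
#' @param gamma Positive-class loss weight; see [compute_class_ratio()].
#' @param settings A [train_settings()] object.
#' @return The fitted `lstm_params`, with attributes `train_loss` (per-epoch),
#'   `val_loss`, `best_epoch` and `epochs_run`.
#' @export
train_lstm <- function(x, y, gamma, settings = train_settings()) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == length(y))
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  n <- length(y)
  params0 <- init_lstm_params(settings$hidden_units, dim(x)[2], settings$seed)
  if (settings$early_stop) {
    val <- stratified_validation_split(y, settings$validation_fraction,
                                       settings$seed + 1L)
    train_idx <- setdiff(seq_len(n), val)
  } else {
    val <- integer(0)
    train_idx <- seq_len(n)
  }
  fit <- cpp_train_lstm(x, as.numeric(y), gamma, pack_params(params0),
                        train_idx - 1L, val - 1L,
                        settings$learning_rate, settings$max_epochs,
                        settings$dropout_rate, settings$batch_size,
                        settings$early_stop, as.integer(settings$seed),
                        settings$beta1, settings$beta2, settings$adam_eps)
  out <- unpack_params(fit$params)
  attr(out, "train_loss") <- as.numeric(fit$train_loss)
  attr(out, "val_loss") <- as.numeric(fit$val_loss)
  attr(out, "best_epoch") <- fit$best_epoch
  attr(out, "epochs_run") <- fit$epochs_run
  out
}

# batched inference on an n x m x T array via the compiled forward pass
forward_scores <- function(params, x) {
  as.numeric(cpp_forward_scores(x, pack_params(params)))
}
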
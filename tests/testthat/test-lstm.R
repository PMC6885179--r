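zero_params <- function(H = 1, m = 1) {
  p <- init_lstm_params(H, m, 1)
  for (nm in c("w_f", "w_i", "w_o", "w_c")) p[[nm]][] <- 0
  p$w_ho[] <- 0; p$b_ho <- 0
  p
}

test_that("lstm_step reproduces hand evaluations of the gated recurrence", {
  p <- zero_params()
  st <- lstm_step(p, 0)
  expect_equal(st$h, 0)   # sigma(0)=0.5, tanh(0)=0
  expect_equal(st$C, 0)

  st <- lstm_step(p, 0, prev = list(h = 0, C = 2))
  expect_equal(st$C, 1)                  # 0.5*2 + 0.5*0
  expect_equal(st$h, 0.5 * tanh(1), tolerance = 1e-12)

  expect_error(lstm_step(p, NaN), "non-finite")
})

test_that("lstm_step and lstm_forward match the scalar-loop oracle", {
  # H=1, m=1 fixed nonzero parameters, checked against the loop oracle
  p <- random_params(1, 1, 3)
  st <- lstm_step(p, 0.7, prev = list(h = 0.1, C = -0.2))
  o <- oracle_step(p, 0.7, 0.1, -0.2)
  expect_equal(st$h, o$h, tolerance = 1e-10)
  expect_equal(st$C, o$C, tolerance = 1e-10)

  # chained over T=3 steps through the read-out
  V <- matrix(c(0.3, -1, 0.5), 1, 3)
  expect_equal(lstm_forward(p, V), oracle_forward(p, V), tolerance = 1e-10)
})

test_that("batched compiled forward agrees with the plain-R contract path", {
  set.seed(10)
  p <- random_params(3, 2, 11)
  X <- array(rnorm(5 * 2 * 4), c(5, 2, 4))
  sc_r <- apply(X, 1, function(v) lstm_forward(p, v))
  sc_c <- elstm:::forward_scores(p, X)
  expect_equal(sc_c, sc_r, tolerance = 1e-12)
})

test_that("read-out saturates and degenerates as the sigmoid dictates", {
  p <- zero_params()
  expect_equal(lstm_forward(p, matrix(rnorm(3), 1)), 0.5)  # h_T = 0
  p$b_ho <- 50
  expect_lt(1 - lstm_forward(p, matrix(0, 1, 3)), 1e-20)
  expect_error(lstm_forward(zero_params(), matrix(0, 1, 0)), "no time steps")
})

test_that("hidden state stays inside (-1, 1) for any finite input", {
  for (s in 1:20) {
    p <- random_params(3, 3, s)
    set.seed(s)
    st <- list(h = numeric(3), C = numeric(3))
    for (t in 1:5) st <- lstm_step(p, rnorm(3, 0, 10), st)
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("weighted cross-entropy weights positives by gamma", {
  expect_equal(weighted_bce(0.5, 0, 5), log(2))
  expect_equal(weighted_bce(0.5, 1, 1), log(2))
  expect_equal(weighted_bce(0.5, 1, 2), 2 * log(2))
  # label 0 independent of gamma; label 1 strictly increasing in gamma
  s <- 0.3
  expect_equal(weighted_bce(s, 0, 1), weighted_bce(s, 0, 9))
  g <- c(0.5, 1, 2, 4, 8)
  losses <- vapply(g, function(gg) weighted_bce(s, 1, gg), numeric(1))
  expect_true(all(diff(losses) > 0))
  # gamma = 1 reduces to plain binary cross-entropy
  for (sc in c(0.1, 0.5, 0.9)) {
    expect_equal(weighted_bce(sc, 1, 1), -log(sc))
    expect_equal(weighted_bce(sc, 0, 1), -log(1 - sc))
  }
  expect_error(weighted_bce(0.5, 1, 0), "positive")
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(weighted_bce(0, 1, 3)))
  expect_true(is.finite(weighted_bce(1, 0, 3)))
})

test_that("Glorot initialisation is deterministic, bounded and correctly shaped", {
  p1 <- init_lstm_params(4, 3, 99)
  p2 <- init_lstm_params(4, 3, 99)
  expect_identical(p1, p2)
  lim <- sqrt(6 / (4 + 3 + 4))
  expect_lte(max(abs(p1$w_f)), lim)
  expect_equal(p1$b_f, numeric(4))
  # reference configuration: 64 units over 25 selected variables -> 64 x 89
  p <- init_lstm_params(64, 25, 1)
  expect_equal(dim(p$w_f), c(64, 89))
})

test_that("training reduces the loss, separates a drifting class, and is reproducible", {
  coh <- separable_cohort(n = 120, d = 4, tt = 6, seed = 21)
  prep <- preprocess_cohort(coh)
  arr <- elstm:::cohort_array(prep$cohort)
  lab <- cohort_labels(coh)
  st <- train_settings(hidden_units = 8, max_epochs = 40, seed = 2)
  fit <- train_lstm(arr, lab, compute_class_ratio(coh), st)
  tl <- attr(fit, "train_loss")
  expect_lt(tail(tl, 1), tl[1])
  expect_gt(auroc(elstm:::forward_scores(fit, arr), lab), 0.95)

  # same seed, same scores on a held-out instance
  fit2 <- train_lstm(arr, lab, compute_class_ratio(coh), st)
  x_new <- arr[1, , , drop = FALSE]
  expect_identical(elstm:::forward_scores(fit, x_new),
                   elstm:::forward_scores(fit2, x_new))

  expect_error(train_lstm(arr, rep(0, length(lab)), 1, st), "both classes")
})

test_that("ensemble-member mode runs exactly max_epochs; early stopping picks the best epoch", {
  coh <- separable_cohort(n = 80, d = 3, tt = 5, seed = 8)
  prep <- preprocess_cohort(coh)
  arr <- elstm:::cohort_array(prep$cohort)
  lab <- cohort_labels(coh)
  fit <- train_lstm(arr, lab, 1, train_settings(hidden_units = 4,
                                                max_epochs = 100, seed = 3))
  expect_identical(attr(fit, "epochs_run"), 100L)
  expect_identical(attr(fit, "best_epoch"), 100L)

  fit_es <- train_lstm(arr, lab, 1,
                       train_settings(hidden_units = 4, max_epochs = 30,
                                      early_stop = TRUE, seed = 3))
  vl <- attr(fit_es, "val_loss")
  expect_identical(attr(fit_es, "best_epoch"), which.min(vl))
})

test_that("parameter serialization round-trips bit-exactly", {
  p <- random_params(3, 2, 17)
  pk <- elstm:::pack_params(p)
  expect_identical(elstm:::unpack_params(pk)[names(p)], p[names(p)])
})
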
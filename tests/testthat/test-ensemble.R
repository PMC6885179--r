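# small fitted model shared across blocks in this file
fit_small <- local({
  coh <- separable_cohort(n = 60, d = 6, tt = 5, seed = 31)
  list(cohort = coh,
       model = elstm(coh, n_learners = 4, hidden_units = 4, epochs = 8,
                     seed = 7))
})

test_that("subset generation draws m distinct variables and N bootstrap instances", {
  cfg <- elstm_config(n_learners = 30, subset_size = 25, master_seed = 2)
  subs <- make_subsets(100, 50, cfg)
  expect_length(subs, 30)
  for (s in subs) {
    expect_length(s$instance_indices, 100)
    expect_length(s$variable_indices, 25)
    expect_identical(anyDuplicated(s$variable_indices), 0L)
    expect_true(all(s$variable_indices >= 1 & s$variable_indices <= 50))
  }
  # m = D degenerates to the full variable set
  full <- make_subsets(10, 5, elstm_config(n_learners = 3, subset_size = 5))
  for (s in full) expect_identical(s$variable_indices, 1:5)
  expect_error(make_subsets(10, 5, elstm_config(n_learners = 1, subset_size = 6)),
               "exceed")
  # default m is floor(D/2)
  half <- make_subsets(10, 9, elstm_config(n_learners = 2))
  expect_length(half[[1]]$variable_indices, 4)
})

test_that("subset randomness is stable per learner index", {
  cfg <- elstm_config(n_learners = 5, subset_size = 3, master_seed = 42)
  s1 <- make_subsets(20, 10, cfg)
  cfg2 <- elstm_config(n_learners = 10, subset_size = 3, master_seed = 42)
  s2 <- make_subsets(20, 10, cfg2)
  # growing the ensemble never perturbs existing learners
  expect_identical(s1, s2[1:5])
})

test_that("bootstrap distinct-instance fraction matches the closed form", {
  # E[distinct]/N = 1 - (1 - 1/N)^N at N = 100
  cfg <- elstm_config(n_learners = 10000, subset_size = 1, master_seed = 9)
  subs <- make_subsets(100, 2, cfg)
  frac <- vapply(subs, function(s) length(unique(s$instance_indices)) / 100,
                 numeric(1))
  expect_equal(mean(frac), 1 - (1 - 1 / 100)^100, tolerance = 0.01)
})

test_that("averaged score obeys mean identities and learner-order invariance", {
  model <- fit_small$model
  coh <- fit_small$cohort
  sc <- predict(model, coh, individual = TRUE)
  avg <- predict(model, coh)
  expect_equal(avg, rowMeans(sc), tolerance = 1e-15)
  expect_true(all(avg >= apply(sc, 1, min) - 1e-12 &
                  avg <= apply(sc, 1, max) + 1e-12))

  perm <- model
  perm$learners <- perm$learners[c(3, 1, 4, 2)]
  expect_equal(predict(perm, coh), avg, tolerance = 1e-12)

  # ensemble of identical learners equals the individual score
  clone <- model
  clone$learners <- model$learners[c(1, 1, 1)]
  expect_equal(predict(clone, coh), sc[, 1], tolerance = 1e-15)
})

test_that("hand-built learners with saturated read-outs average as computed", {
  # three zero-weight learners with read-out biases 0, 50, -50:
  # scores 0.5, ~1, ~0 -> mean 0.5
  mk <- function(b) {
    p <- init_lstm_params(2, 2, 1)
    for (nm in c("w_f", "w_i", "w_o", "w_c")) p[[nm]][] <- 0
    p$w_ho[] <- 0; p$b_ho <- b
    list(params = p, variable_indices = 1:2, seed = 1L)
  }
  model <- fit_small$model
  model$learners <- list(mk(0), mk(50), mk(-50))
  model$stats <- structure(list(mean = c(0, 0), std = c(1, 1)),
                           class = "norm_stats")
  model$variable_names <- c("a", "b")
  s <- patient_series("x", matrix(rnorm(6), 2, 3), label = 0)
  expect_equal(predict(model, s), 0.5, tolerance = 1e-9)
})

test_that("P = 1 with m = D reduces to a single LSTM on the bootstrap sample", {
  coh <- fit_small$cohort
  d <- length(coh$variable_names)
  model <- elstm(coh, n_learners = 1, subset_size = d, hidden_units = 4,
                 epochs = 6, seed = 13)
  # reproduce the one learner by hand from the same derived seed
  sub <- make_subsets(length(coh), d, model$config)[[1]]
  prep <- preprocess_cohort(coh)
  arr <- elstm:::cohort_array(prep$cohort)
  st <- model$config$train_settings
  st$seed <- sub$seed
  params <- train_lstm(arr[sub$instance_indices, , , drop = FALSE],
                       cohort_labels(coh)[sub$instance_indices],
                       compute_class_ratio(coh), st)
  manual <- elstm:::forward_scores(params, arr)
  expect_equal(unname(predict(model, coh)), manual, tolerance = 1e-12)
})

test_that("ensemble training is reproducible and single-class resamples are redrawn", {
  coh <- fit_small$cohort
  m1 <- elstm(coh, n_learners = 3, hidden_units = 4, epochs = 5, seed = 5)
  m2 <- elstm(coh, n_learners = 3, hidden_units = 4, epochs = 5, seed = 5)
  expect_identical(predict(m1, coh), predict(m2, coh))

  # extreme imbalance (11:1): single-class bootstrap draws occur with
  # probability (11/12)^12 ~ 0.35 per learner and must be redrawn
  mk <- function(i, lab) patient_series(paste0("s", i),
                                        matrix(rnorm(8, lab), 2, 4), lab)
  set.seed(1)
  skewed <- new_cohort(c(lapply(1:11, mk, lab = 0), list(mk(12, 1))),
                       c("a", "b"))
  expect_equal(compute_class_ratio(skewed), 11)
  m3 <- elstm(skewed, n_learners = 6, hidden_units = 3, epochs = 4, seed = 2)
  expect_length(m3$learners, 6)
  expect_true(all(is.finite(predict(m3, skewed))))
})

test_that("model bundles round-trip bit-exactly through disk", {
  model <- fit_small$model
  dir <- tempfile("bundle")
  save_elstm(model, dir)
  back <- load_elstm(dir)
  expect_identical(back$gamma, model$gamma)
  expect_identical(back$variable_names, model$variable_names)
  for (p in seq_along(model$learners)) {
    expect_identical(back$learners[[p]]$variable_indices,
                     model$learners[[p]]$variable_indices)
    a <- model$learners[[p]]$params; attributes(a) <- attributes(a)["names"]
    b <- back$learners[[p]]$params; attributes(b) <- attributes(b)["names"]
    expect_identical(unclass(b), unclass(a))
  }
  coh <- fit_small$cohort
  expect_identical(predict(back, coh), unname(predict(model, coh)))
  unlink(dir, recursive = TRUE)
})

test_that("accessor methods expose fitted scores, residuals and simulations", {
  model <- fit_small$model
  coh <- fit_small$cohort
  expect_equal(fitted(model), model$fitted)
  expect_equal(residuals(model), cohort_labels(coh) - model$fitted)
  sims <- simulate(model, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(coh), 3))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(model), "base learner")
  expect_output(print(summary(model)), "AUROC")
})
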
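test_that("linear interpolation fills internal gaps and extends edges", {
  s <- patient_series("a", matrix(c(1, NA, 3), 1), label = 0)
  expect_equal(impute_linear(s)$values[1, ], c(1, 2, 3))

  s <- patient_series("b", matrix(c(NA, 2, NA), 1), label = 0)
  expect_equal(impute_linear(s)$values[1, ], c(2, 2, 2))

  # line through (1,0) and (4,6) evaluated at t = 2, 3
  s <- patient_series("c", matrix(c(0, NA, NA, 6), 1), label = 1)
  expect_equal(impute_linear(s)$values[1, ], c(0, 2, 4, 6))
})

test_that("imputation is idempotent and never alters observed entries", {
  coh <- generate_cohort(synth_config(n_patients = 30, D = 5, T = 8,
                                      missing_rate = 0.3, seed = 4))
  for (p in coh$patients[1:10]) {
    if (any(rowSums(p$observed) == 0)) next  # needs cohort-level fill
    once <- impute_linear(p)
    expect_true(all(once$observed))
    expect_equal(impute_linear(once)$values, once$values)
    expect_equal(once$values[p$observed], p$values[p$observed])
  }
})

test_that("imputation rejects a series with no data and all-missing variables without a fill", {
  empty <- patient_series("e", matrix(NA_real_, 2, 3), label = 0,
                          observed = matrix(FALSE, 2, 3))
  expect_error(impute_linear(empty), "no observed data")
  part <- patient_series("p", rbind(c(1, 2, 3), c(NA, NA, NA)), label = 0)
  expect_error(impute_linear(part), "all_missing_fill")
  filled <- impute_linear(part, all_missing_fill = c(0, 9))
  expect_equal(filled$values[2, ], c(9, 9, 9))
})

test_that("normalization stats pool over patients and days with the sample denominator", {
  mk <- function(id, v) patient_series(id, matrix(v, 1), label = 0)
  coh <- new_cohort(list(mk("a", c(0, 0)),
                         patient_series("b", matrix(c(2, 2), 1), label = 1)),
                    "v")
  st <- fit_normalization(coh)
  expect_equal(st$mean, 1)
  expect_equal(st$std, sd(c(0, 0, 2, 2)))  # n-1 denominator

  one <- new_cohort(list(mk("a", c(1, 2, 3))), "v")
  expect_equal(fit_normalization(one)$mean, 2)
})

test_that("zero-variance variables normalise to 0 via the std floor", {
  coh <- new_cohort(list(patient_series("a", matrix(c(5, 5, 5), 1), label = 0),
                         patient_series("b", matrix(c(5, 5, 5), 1), label = 1)),
                    "v")
  st <- fit_normalization(coh)
  expect_equal(st$std, 0)
  z <- apply_normalization(coh$patients[[1]], st)
  expect_equal(unname(z$values[1, ]), c(0, 0, 0))
})

test_that("apply_normalization computes (x - mean)/std per variable", {
  s <- patient_series("a", rbind(c(3, 3), c(10, 10)), label = 0)
  st <- structure(list(mean = c(1, 10), std = c(2, 1)), class = "norm_stats")
  z <- apply_normalization(s, st)
  expect_equal(unname(z$values), rbind(c(1, 1), c(0, 0)))
  bad <- structure(list(mean = 0, std = 1), class = "norm_stats")
  expect_error(apply_normalization(s, bad), "mismatch")
})

test_that("preprocessing yields pooled mean 0 / sd 1 per variable on the training cohort", {
  coh <- generate_cohort(synth_config(n_patients = 40, D = 4, T = 6,
                                      missing_rate = 0.15, seed = 9))
  prep <- preprocess_cohort(coh)
  arr <- elstm:::cohort_array(prep$cohort)
  for (d in 1:4) {
    x <- as.vector(arr[, d, ])
    expect_equal(mean(x), 0, tolerance = 1e-9)
    expect_equal(sd(x), 1, tolerance = 1e-9)
  }
  # test-mode reuse: stats must come from the supplied object, not the data
  prep2 <- preprocess_cohort(coh, stats = prep$stats)
  expect_identical(prep2$stats, prep$stats)
})

test_that("class ratio is N_neg / N_pos", {
  expect_equal(compute_class_ratio(worked_fixture()), 2)
  mk <- function(lab, i) patient_series(paste0("p", i), matrix(1, 1, 2), lab)
  coh <- new_cohort(c(lapply(1:3, mk, lab = 0), lapply(4:7, mk, lab = 1)), "v")
  expect_equal(compute_class_ratio(coh), 0.75)
  # the motivating cohort: 16253 survivors, 2162 deaths
  expect_equal(16253 / 2162, 7.518, tolerance = 1e-4)
  all_neg <- new_cohort(lapply(1:3, mk, lab = 0), "v")
  expect_error(compute_class_ratio(all_neg), "no positive")
  # exact integer identity
  lab <- cohort_labels(coh)
  expect_identical(compute_class_ratio(coh) * sum(lab == 1), sum(lab == 0) + 0)
})

test_that("cohort CSV round-trips values, labels and missingness", {
  coh <- generate_cohort(synth_config(n_patients = 12, D = 3, T = 4,
                                      missing_rate = 0.2, seed = 5))
  dp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, dp, lp)
  back <- read_cohort_csv(dp, lp, variable_names = coh$variable_names, T = 4)
  expect_equal(length(back), length(coh))
  expect_equal(cohort_labels(back), cohort_labels(coh))
  for (i in seq_along(coh$patients)) {
    expect_equal(back$patients[[i]]$observed, coh$patients[[i]]$observed,
                 ignore_attr = TRUE)
    obs <- coh$patients[[i]]$observed
    expect_equal(back$patients[[i]]$values[obs], coh$patients[[i]]$values[obs],
                 tolerance = 1e-12)
  }
  unlink(c(dp, lp))
})

test_that("CSV reader validates day range and variable names", {
  dp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,day,variable,value", "p1,1,hr,60", "p1,99,hr,61"), dp)
  writeLines(c("patient_id,label", "p1,0"), lp)
  expect_error(read_cohort_csv(dp, lp, variable_names = "hr", T = 10), "day")
  writeLines(c("patient_id,day,variable,value", "p1,1,bogus,60"), dp)
  expect_error(read_cohort_csv(dp, lp, variable_names = "hr"), "unknown variable")
  unlink(c(dp, lp))
})
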
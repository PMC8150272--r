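test_that("normalization maps endpoints, midpoints and round-trips", {
  b <- vi_bounds(c(0, -2, 5), c(10, 2, 5))   # third feature degenerate
  expect_equal(normalize(c(0, -2, 5), b), c(0, 0, 0.5))
  expect_equal(normalize(c(10, 2, 5), b), c(1, 1, 0.5))
  expect_equal(normalize(c(5, 0, 5), b), c(0.5, 0.5, 0.5))
  # round-trip identity on random in-bounds vectors
  withr::with_seed(1, {
    for (i in 1:20) {
      lo <- runif(6, -10, 0); hi <- lo + runif(6, 0.1, 10)
      bb <- vi_bounds(lo, hi)
      x <- runif(6, lo, hi)
      expect_equal(denormalize(normalize(x, bb), bb), x, tolerance = 1e-12)
    }
  })
  expect_error(vi_bounds(c(0, 1), c(1, 0)), "lower")
})

test_that("training recovers a noiseless synthetic cohort (R^2 > 0.9 per output)", {
  sim <- generate_cohort(cohort_spec(n_patients = 20, records_per_patient = 30,
                                     sigma = 0, missing_fraction = 0,
                                     healthy_fraction = 0, seed = 21))
  m <- train_network(sim$observed, seed = 8, epochs = 2000, patience = 2000)
  # held-out partition per the model's own split
  test_idx <- withr::with_seed(8, {
    n <- nrow(sim$observed); idx <- sample.int(n)
    n_tr <- round(0.7 * n); n_va <- min(round(0.15 * n), n - n_tr - 1L)
    idx[-seq_len(n_tr + n_va)]
  })
  pred <- predict(m, sim$observed[test_idx, vi_setting_fields()])
  truth <- sim$observed[test_idx, vi_observation_fields()]
  for (f in vi_observation_fields()) {
    r2 <- 1 - sum((pred[[f]] - truth[[f]])^2) /
      sum((truth[[f]] - mean(truth[[f]]))^2)
    expect_gt(r2, 0.9)
  }
})

test_that("constant outputs are learned with near-zero total error", {
  df <- random_records(60, seed = 3)
  df[vi_observation_fields()] <- lapply(
    c(Vti = 300, Cdyn = 25, EtCO2 = 40, SpO2 = 97, HR = 90, BP = 85,
      Temp = 38.5), rep, nrow(df))
  m <- train_network(df, seed = 2, epochs = 800, patience = 800)
  # 60 records x 7 outputs: SSE below 0.01 is per-cell RMSE < 0.5 % of range
  expect_lt(m$total_error, 0.01)
  p <- predict(m, df[1, vi_setting_fields()])
  expect_equal(p$Vti, 300, tolerance = 1e-2)
})

test_that("training and prediction are deterministic under a fixed seed", {
  coh <- desk_cohort()$observed[1:120, ]
  m1 <- train_network(coh, seed = 13, epochs = 300, patience = 300)
  m2 <- train_network(coh, seed = 13, epochs = 300, patience = 300)
  expect_identical(m1$total_error, m2$total_error)
  s <- coh[5, vi_setting_fields()]
  expect_identical(predict(m1, s), predict(m1, s))
  expect_true(all(is.finite(unlist(predict(m1, s)))))
  expect_error(predict(m1, c(a = 1)), "missing")
})

test_that("training guards reject unusable cohorts", {
  expect_error(train_network(random_records(10)), "too small")
  holey <- random_records(40)
  holey$Vti[3] <- NA
  expect_error(train_network(holey), "missing cells")
})

test_that("ensemble selection keeps the k best by total error", {
  ens <- desk_ensemble()
  errs <- vapply(ens$models, function(m) m$total_error, numeric(1))
  expect_length(ens$models, 3)
  expect_false(is.unsorted(errs))                       # ascending
  others <- setdiff(ens$all_errors[!is.na(ens$all_errors)], errs)
  if (length(others)) expect_true(max(errs) <= min(others))  # dominance
  expect_true(max(errs) <= stats::median(ens$all_errors, na.rm = TRUE))
  expect_error(train_ensemble(desk_cohort()$observed, n_candidates = 2, k = 5),
               "n_candidates >= k")
})

test_that("surrogate fidelity degrades monotonically with observation noise", {
  rmse <- vapply(c(0, 0.01, 0.05), function(s) {
    sim <- generate_cohort(cohort_spec(n_patients = 15, records_per_patient = 20,
                                       sigma = s, missing_fraction = 0,
                                       healthy_fraction = 0, seed = 31))
    m <- train_network(sim$observed, seed = 9, epochs = 1200, patience = 1200)
    # held-out truth: fresh noiseless records from the same world
    fresh <- generate_cohort(cohort_spec(n_patients = 10, records_per_patient = 10,
                                         sigma = 0, missing_fraction = 0,
                                         healthy_fraction = 0, seed = 32))
    pred <- predict(m, fresh$truth[, vi_setting_fields()])
    Yn <- normalize(as.matrix(fresh$truth[, vi_observation_fields()]),
                    m$output_bounds)
    Pn <- normalize(as.matrix(pred), m$output_bounds)
    sqrt(mean((Yn - Pn)^2))
  }, numeric(1))
  expect_false(is.unsorted(rmse))
  expect_lt(rmse[1], 0.05)
})

test_that("surrogate and ensemble archives round-trip through JSON", {
  ens <- desk_ensemble()
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  expect_equal(length(back$models), ens$k)
  s <- desk_cohort()$observed[7, vi_setting_fields()]
  expect_equal(predict(back$models[[1]], s), predict(ens$models[[1]], s),
               tolerance = 1e-12)
  expect_equal(back$models[[2]]$total_error, ens$models[[2]]$total_error,
               tolerance = 1e-12)
})
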
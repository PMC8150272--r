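test_that("fitness is half the sum of squared normalized residuals", {
  toy <- toy_linear_surrogate()
  # independent oracle, written directly from the definition
  oracle <- function(s, tgt) {
    pred <- as.numeric(predict(toy, s)[1, ])   # unit bounds: already normalized
    0.5 * sum((pred - tgt)^2)
  }
  withr::with_seed(4, {
    for (i in 1:100) {
      s <- stats::setNames(runif(8), vi_setting_fields())
      tgt <- stats::setNames(runif(7), vi_observation_fields())
      target <- inversion_target(tgt, c(age = s[["age"]], weight = s[["weight"]]))
      expect_equal(fitness(s, toy, target, warn = FALSE), oracle(s, tgt),
                   tolerance = 1e-12)
    }
  })
  # prediction equal to target: exactly zero
  s0 <- stats::setNames(rep(0.4, 8), vi_setting_fields())
  tgt0 <- stats::setNames(as.numeric(predict(toy, s0)[1, ]),
                          vi_observation_fields())
  expect_identical(fitness(s0, toy, inversion_target(tgt0, c(age = 0.4)),
                           warn = FALSE), 0)
  # single-feature residual of 0.2 contributes 0.5 * 0.04
  tgt1 <- tgt0; tgt1[1] <- tgt1[1] + 0.2
  expect_equal(fitness(s0, toy, inversion_target(tgt1, c(age = 0.4)),
                       warn = FALSE), 0.02, tolerance = 1e-12)
  # out-of-range normalized target is permitted but flagged
  expect_warning(fitness(s0, toy, inversion_target(tgt0 + 5, c(age = 0.4))),
                 "outside \\[0, 1\\]")
})

test_that("target construction validates its inputs", {
  expect_error(inversion_target(c(Vti = NA, Cdyn = 1, EtCO2 = 1, SpO2 = 1,
                                  HR = 1, BP = 1, Temp = 1), c(age = 1)),
               "finite")
  expect_error(inversion_target(rep(1, 7), c(height = 2)), "not setting fields")
})

test_that("a trial inverts an invertible toy surrogate", {
  toy <- toy_linear_surrogate()
  b <- toy$input_bounds
  s_star <- stats::setNames(seq(0.25, 0.6, length.out = 8), vi_setting_fields())
  tgt <- stats::setNames(as.numeric(predict(toy, s_star)[1, ]),
                         vi_observation_fields())
  target <- inversion_target(tgt, c(age = s_star[["age"]],
                                    weight = s_star[["weight"]]))
  cfg <- gpso_config(population = 100, n_groups = 10,
                     max_iterations = 300, tolerance = 1e-10)
  res <- run_trial(target, toy, cfg, b, seed = 6)
  expect_lt(res$best_fitness, 1e-4)
  expect_equal(unname(res$best_settings), unname(s_star), tolerance = 0.05)
  # frozen dimensions sit exactly at the known inputs
  expect_identical(res$best_settings[["age"]], s_star[["age"]])
  expect_identical(res$best_settings[["weight"]], s_star[["weight"]])

  # all eight dimensions fixed: the answer is the known input
  all_fixed <- s_star
  res2 <- run_trial(inversion_target(tgt, all_fixed), toy, cfg, b, seed = 1)
  expect_equal(res2$best_settings, s_star)
  expect_equal(res2$best_fitness,
               fitness(s_star, toy, target, warn = FALSE), tolerance = 1e-12)
})

test_that("campaigns aggregate trials x networks with sound statistics", {
  toy <- toy_linear_surrogate()
  b <- toy$input_bounds
  s_star <- stats::setNames(rep(0.5, 8), vi_setting_fields())
  tgt <- stats::setNames(as.numeric(predict(toy, s_star)[1, ]),
                         vi_observation_fields())
  target <- inversion_target(tgt, c(age = 0.5, weight = 0.5))
  cfg <- gpso_config(population = 60, n_groups = 6,
                     max_iterations = 80, tolerance = 0)

  rep1 <- run_campaign(target, list(toy), cfg, b, n_trials = 1, seed = 2)
  expect_equal(rep1$stats$min, rep1$stats$max)
  expect_equal(rep1$stats$mean, rep1$stats$min)
  expect_equal(rep1$stats$sd, rep(0, 8))

  rep4 <- run_campaign(target, list(toy, toy), cfg, b, n_trials = 3, seed = 2)
  expect_equal(nrow(rep4$trials), 6)            # trials x networks
  expect_true(all(rep4$stats$min <= rep4$stats$mean + 1e-12))
  expect_true(all(rep4$stats$mean <= rep4$stats$max + 1e-12))
  expect_true(all(rep4$stats$sd >= 0))
  # statistics are recomputable from the stored trial table
  sf <- vi_setting_fields()
  expect_equal(rep4$stats$mean, unname(colMeans(rep4$trials[, sf])))
  expect_equal(rep4$stats$min, unname(apply(rep4$trials[, sf], 2, min)))
  # bounds and fixed dimensions respected in every trial
  for (f in sf) {
    expect_true(all(rep4$trials[[f]] >= b$lower[f] - 1e-12))
    expect_true(all(rep4$trials[[f]] <= b$upper[f] + 1e-12))
  }
  expect_true(all(rep4$trials$age == 0.5))
  expect_true(all(rep4$trials$weight == 0.5))
  # per-network breakdown covers both readings of the aggregation
  expect_length(rep4$per_network, 2)
  expect_error(run_campaign(target, list(), cfg, b), "non-empty")
})

test_that("identical seed and config give byte-identical written reports", {
  toy <- toy_linear_surrogate()
  b <- toy$input_bounds
  tgt <- stats::setNames(as.numeric(predict(
    toy, stats::setNames(rep(0.5, 8), vi_setting_fields()))[1, ]),
    vi_observation_fields())
  target <- inversion_target(tgt, c(age = 0.5, weight = 0.5))
  cfg <- gpso_config(population = 40, n_groups = 4,
                     max_iterations = 40, tolerance = 0)
  r1 <- run_campaign(target, list(toy), cfg, b, n_trials = 3, seed = 11)
  r2 <- run_campaign(target, list(toy), cfg, b, n_trials = 3, seed = 11)
  expect_identical(r1$trials, r2$trials)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(r1, d1); write_report(r2, d2)
  for (f in c("report.json", "report_trials.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("the PIP projection restricts the search to consistent pressures", {
  toy <- toy_linear_surrogate()
  b <- toy$input_bounds
  tgt <- stats::setNames(rep(0.5, 7), vi_observation_fields())
  target <- inversion_target(tgt, c(age = 0.5, weight = 0.5))
  cfg <- gpso_config(population = 40, n_groups = 4,
                     max_iterations = 30, tolerance = 0)
  r <- run_campaign(target, list(toy), cfg, b, n_trials = 2, seed = 3,
                    project_pip = TRUE)
  # unit box: SetP + PEEP can exceed the PIP bound, where clamping wins
  expect_equal(r$trials$PIP,
               pmin(r$trials$SetP + r$trials$PEEP, b$upper["PIP"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
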
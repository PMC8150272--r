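test_that("config validation enforces the swarm contract", {
  cfg <- gpso_config()
  expect_equal(cfg$population, 2000L)
  expect_equal(cfg$n_groups, 50L)
  expect_equal(cfg$population / cfg$n_groups, 40)   # 50 groups of 40
  expect_equal(c(cfg$omega, cfg$c1, cfg$c2, cfg$c3), c(0.8, 1.2, 1.2, 1.2))

  expect_error(gpso_config(population = 10, n_groups = 3), "divisible")
  expect_error(gpso_config(population = 0), "positive")
  expect_error(gpso_config(max_iterations = 0), "max_iterations")
  expect_error(gpso_config(tolerance = -1), "tolerance")
  expect_error(gpso_config(omega = 1.5), "omega")

  t2 <- gpso_config(profile = "table2")
  expect_equal(c(t2$max_iterations, t2$tolerance), c(100, 0.01))
  tx <- gpso_config(profile = "text")
  expect_equal(c(tx$max_iterations, tx$tolerance), c(1000, 1e-4))
})

test_that("velocity rule matches hand evaluation and degenerates correctly", {
  m <- function(v) matrix(v, 1, 1)
  # omega 0.8, all c 1.2, forced r = 1, v = 0, x = 0, pbest 1, gbest 2,
  # ubest 3 -> 1.2*1 + 1.2*2 + 1.2*3 = 7.2
  v1 <- ventinvert:::gpso_velocity(m(0), m(0), m(1), m(2), m(3),
                                   0.8, 1.2, 1.2, 1.2, 1, 1, 1)
  expect_equal(as.numeric(v1), 7.2)
  # particle sitting at pbest = gbest = ubest with zero velocity stays put
  v0 <- ventinvert:::gpso_velocity(m(0), m(5), m(5), m(5), m(5),
                                   0.8, 1.2, 1.2, 1.2, 1, 1, 1)
  expect_identical(as.numeric(v0), 0)
  # one group, tied draws: three-term rule equals classic PSO with c2' = c2+c3
  set.seed(1)
  V <- matrix(rnorm(12), 4); X <- matrix(rnorm(12), 4)
  P <- matrix(rnorm(12), 4); G <- matrix(rnorm(12), 4)
  r1 <- runif(4); r2 <- runif(4)
  expect_identical(
    ventinvert:::gpso_velocity(V, X, P, G, G, 0.8, 1.2, 1.2, 1.2, r1, r2, r2),
    ventinvert:::pso_velocity(V, X, P, G, 0.8, 1.2, 2.4, r1, r2))
})

test_that("single-group GPSO with tied draws reduces to classic PSO bit-for-bit", {
  b <- vi_bounds(rep(-5, 8), rep(5, 8))
  g <- gpso_optimize(sphere, b,
                     gpso_config(population = 40, n_groups = 1,
                                 tie_leader_draws = TRUE,
                                 max_iterations = 100, tolerance = 0),
                     seed = 7, keep_history = TRUE)
  p <- pso_optimize(sphere, b,
                    gpso_config(population = 40, n_groups = 1,
                                c2 = 2.4, c3 = 0,
                                max_iterations = 100, tolerance = 0),
                    seed = 7, keep_history = TRUE)
  expect_identical(g$history, p$history)   # every position, every iteration
  expect_identical(g$best_fitness_per_iteration, p$best_fitness_per_iteration)
})

test_that("degenerate configurations behave as contracted", {
  # collapsed box: the single feasible point everywhere
  bc <- vi_bounds(rep(2, 3), rep(2, 3))
  tr <- gpso_optimize(sphere, bc,
                      gpso_config(population = 8, n_groups = 2,
                                  max_iterations = 5, tolerance = 0),
                      seed = 1, keep_history = TRUE)
  expect_equal(unname(tr$final_best_position), rep(2, 3))
  for (H in tr$history) expect_true(all(H == 2))

  # constant objective: flat trace, runs to the iteration cap
  flat <- function(X) rep(3.5, nrow(X))
  tr2 <- gpso_optimize(flat, vi_bounds(0, 1),
                       gpso_config(population = 6, n_groups = 2,
                                   max_iterations = 7, tolerance = 0),
                       seed = 1)
  expect_equal(tr2$best_fitness_per_iteration, rep(3.5, 7))
  expect_equal(tr2$terminated_by, "iteration_cap")

  # groups are a contiguous equal partition of particle indices
  expect_equal(tr$group, rep(1:2, each = 4))

  # one member per group still runs (gbest = own pbest)
  tr3 <- gpso_optimize(sphere, vi_bounds(rep(-1, 2), rep(1, 2)),
                       gpso_config(population = 12, n_groups = 12,
                                   max_iterations = 30, tolerance = 0),
                       seed = 2)
  expect_true(is.finite(tr3$final_best_fitness))

  # non-finite objective values never become leaders
  spiky <- function(X) ifelse(X[, 1] > 0, NaN, rowSums(X^2))
  tr4 <- gpso_optimize(spiky, vi_bounds(-1, 1),
                       gpso_config(population = 20, n_groups = 4,
                                   max_iterations = 30, tolerance = 0),
                       seed = 3)
  expect_true(is.finite(tr4$final_best_fitness))
  expect_gt(tr4$n_nonfinite, 0)
})

test_that("traces respect feasibility, monotonicity, leader dominance, seeds", {
  b <- vi_bounds(c(-3, 0, 10), c(4, 1, 30))
  cfg <- gpso_config(population = 30, n_groups = 5,
                     max_iterations = 60, tolerance = 0)
  for (s in 1:3) {
    obj <- withr::with_seed(s, {
      A <- matrix(rnorm(9), 3); ctr <- runif(3, c(-3, 0, 10), c(4, 1, 30))
      function(X) rowSums((sweep(X, 2, ctr) %*% A)^2)
    })
    tr <- gpso_optimize(obj, b, cfg, fixed = c("3" = 20), seed = s,
                        keep_history = TRUE)
    # feasibility + frozen dimension, across the full trace
    for (H in tr$history) {
      expect_true(all(sweep(H, 2, b$lower, ">=") & sweep(H, 2, b$upper, "<=")))
      expect_true(all(H[, 3] == 20))
    }
    # best-so-far record never rises
    expect_true(all(diff(tr$best_fitness_per_iteration) <= 0))
    # universal best dominates all personal bests
    expect_equal(tr$final_best_fitness, min(tr$pbest_fitness))
    # reproducibility
    tr2 <- gpso_optimize(obj, b, cfg, fixed = c("3" = 20), seed = s)
    expect_identical(tr2$best_fitness_per_iteration,
                     tr$best_fitness_per_iteration)
    expect_identical(tr2$final_best_position, tr$final_best_position)
  }
})

test_that("desk-scale swarms find the sphere optimum", {
  b <- vi_bounds(rep(-5, 2), rep(5, 2))
  tr <- pso_optimize(sphere, b,
                     gpso_config(population = 50, n_groups = 1,
                                 max_iterations = 500, tolerance = 1e-6),
                     seed = 4)
  expect_lt(tr$final_best_fitness, 1e-4)
  tr8 <- gpso_optimize(sphere, vi_bounds(rep(-5, 8), rep(5, 8)),
                       gpso_config(population = 200, n_groups = 10,
                                   max_iterations = 1000, tolerance = 1e-6),
                       seed = 5)
  expect_lt(tr8$final_best_fitness, 1e-4)
})

test_that("vectorize_objective lifts scalar functions", {
  f <- vectorize_objective(function(x) sum(x^2) + 1)
  X <- matrix(1:6, 3, 2)
  expect_equal(f(X), c(1 + 16 + 1, 4 + 25 + 1, 9 + 36 + 1))
})
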
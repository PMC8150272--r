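#' GPSO configuration
#'
#' The Graded Particle Swarm Optimizer divides the swarm into equal-sized
#' groups; each group has a leader (its best-so-far member, `gbest`) and the
#' best of all leaders is the universal leader (`ubest`).  The velocity
#' update adds a universal-leader attraction term to the classic two-term
#' rule:
#'
#' `v[t+1] = omega*v[t] + r1*c1*(pbest - x) + r2*c2*(gbest - x) + r3*c3*(ubest - x)`
#'
#' with `r1, r2, r3` fresh uniform(0,1) draws each term/particle/iteration.
#'
#' Defaults reproduce the published full-scale protocol: population 2000,
#' 50 groups, momentum `omega = 0.8`, `c1 = c2 = c3 = 1.2`.  Two named
#' termination profiles exist because the source protocol states both:
#' `"table2"` (100 iterations or fitness below 0.01) and `"text"` (1000
#' iterations or fitness below 1e-4).
#'
#' @param population Swarm size; must be divisible by `n_groups`.
#' @param n_groups Number of equal-sized groups.
#' @param omega Momentum (inertia) weight in `[0, 1]`.
#' @param c1,c2,c3 Personal, group-leader and universal-leader influence
#'   constants.
#' @param max_iterations Iteration cap (>= 1).
#' @param tolerance Stop once the best fitness drops below this value
#'   (>= 0; set 0 to always run to the cap).
#' @param r_mode `"scalar"` draws one r per term per particle per iteration
#'   (matching the scalar update notation); `"per_dimension"` draws
#'   independently per dimension.
#' @param tie_leader_draws If `TRUE`, the group-leader and universal-leader
#'   terms share a single draw (`r3 := r2`).  With `n_groups = 1` this makes
#'   GPSO consume the random stream exactly like classic PSO and reduce to it
#'   bit-for-bit with `c2' = c2 + c3` (the reduction oracle used in tests).
#' @param profile Optional shorthand: `"table2"` or `"text"` override
#'   `max_iterations`/`tolerance` as above.
#' @return A list of class `gpso_config`.
#' @seealso [gpso_optimize()], [pso_optimize()]
#' @export
gpso_config <- function(population = 2000L, n_groups = 50L,
                        omega = 0.8, c1 = 1.2, c2 = 1.2, c3 = 1.2,
                        max_iterations = 100L, tolerance = 0.01,
                        r_mode = c("scalar", "per_dimension"),
                        tie_leader_draws = FALSE,
                        profile = NULL) {
  r_mode <- match.arg(r_mode)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("table2", "text"))
    if (profile == "table2") { max_iterations <- 100L; tolerance <- 0.01 }
    if (profile == "text")   { max_iterations <- 1000L; tolerance <- 1e-4 }
  }
  population <- as.integer(population)
  n_groups <- as.integer(n_groups)
  if (population < 1L || n_groups < 1L) {
    stop("population and n_groups must be positive", call. = FALSE)
  }
  if (population %% n_groups != 0L) {
    stop("population (", population, ") must be divisible by n_groups (",
         n_groups, ")", call. = FALSE)
  }
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]", call. = FALSE)
  structure(list(population = population, n_groups = n_groups,
                 omega = omega, c1 = c1, c2 = c2, c3 = c3,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, r_mode = r_mode,
                 tie_leader_draws = isTRUE(tie_leader_draws),
                 profile = if (is.null(profile)) NA_character_ else profile),
            class = "gpso_config")
}

#' @export
print.gpso_config <- function(x, ...) {
  cat("<gpso_config> population ", x$population, " in ", x$n_groups,
      " groups | omega ", x$omega, ", c1 ", x$c1, ", c2 ", x$c2, ", c3 ",
      x$c3, "\n  stop: ", x$max_iterations, " iterations or fitness < ",
      x$tolerance, " | r_mode ", x$r_mode, "\n", sep = "")
  invisible(x)
}

#' Wrap a scalar objective for swarm evaluation
#'
#' Objectives passed to the optimizers are evaluated on a whole swarm at
#' once: they receive an `n x d` matrix of positions and must return `n`
#' fitness values.  This helper lifts an ordinary `function(x) -> scalar`.
#'
#' @param f Function of a single numeric vector returning one number.
#' @return A vectorized objective.
#' @export
vectorize_objective <- function(f) {
  function(X) apply(X, 1L, f)
}

# evaluate the swarm; non-finite values become +Inf (counted, never a leader)
eval_swarm <- function(objective, X) {
  f <- as.numeric(objective(X))
  if (length(f) != nrow(X)) {
    stop("objective must return one fitness value per swarm row", call. = FALSE)
  }
  bad <- !is.finite(f)
  if (any(bad)) f[bad] <- Inf
  list(f = f, n_nonfinite = sum(bad))
}

# r draws for one attraction term: vector (scalar mode) or matrix
draw_r <- function(n, d, r_mode) {
  if (r_mode == "scalar") stats::runif(n) else
    matrix(stats::runif(n * d), n, d)
}

# group bests from pbest values: first index wins ties (lowest particle index)
group_argbest <- function(pf, group) {
  vapply(seq_len(max(group)), function(j) {
    idx <- which(group == j)
    idx[which.min(pf[idx])]
  }, integer(1))
}

new_trace <- function(best, position, iters, why, seed, config, extra = list()) {
  structure(c(list(best_fitness_per_iteration = best,
                   final_best_position = position,
                   final_best_fitness = best[length(best)],
                   iterations_used = iters,
                   terminated_by = why,
                   seed = seed,
                   config = config), extra),
            class = "gpso_trace")
}

#' @export
print.gpso_trace <- function(x, ...) {
  cat("<gpso_trace> ", x$iterations_used, " iterations (",
      x$terminated_by, "), best fitness ",
      format(x$final_best_fitness, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Run the Graded Particle Swarm Optimizer
#'
#' Minimizes `objective` over the box `bounds`.  Positions start uniform in
#' the box, velocities at zero; each iteration evaluates the swarm, updates
#' personal/group/universal bests (best-so-far with ties broken by lowest
#' particle index), applies the three-term velocity update, moves, and clamps
#' every component to the nearest bound.  Dimensions listed in `fixed` are
#' frozen: velocity identically 0, position pinned to the given value (used
#' to hold known inputs such as age and weight during inversion).
#'
#' @param objective Vectorized objective: `n x d` matrix -> `n` fitnesses
#'   (see [vectorize_objective()]).  Non-finite values are treated as `+Inf`.
#' @param bounds A [vi_bounds()] defining the search box.
#' @param config A [gpso_config()].
#' @param fixed Optional named numeric vector (names = dimension names) or a
#'   numeric vector with integer names/indices mapping dimension -> value.
#' @param transform Optional function applied to the clamped position matrix
#'   after every move (e.g. projecting `PIP = SetP + PEEP`); its output is
#'   re-clamped and re-pinned.
#' @param seed Integer seed; the run is a pure function of
#'   `(seed, config, bounds, objective)`.
#' @param keep_history If `TRUE`, store the position matrix after every
#'   iteration (memory heavy; meant for invariant checking).
#' @return A `gpso_trace`: per-iteration best fitness (non-increasing), final
#'   best position/fitness, iterations used, termination reason, seed and
#'   config, plus `n_nonfinite` (objective values coerced to `+Inf`).
#' @examples
#' sphere <- function(X) rowSums(X^2)
#' tr <- gpso_optimize(sphere, vi_bounds(rep(-5, 4), rep(5, 4)),
#'                     gpso_config(population = 60, n_groups = 6,
#'                                 max_iterations = 200, tolerance = 1e-8),
#'                     seed = 1)
#' @export
gpso_optimize <- function(objective, bounds, config, fixed = NULL,
                          transform = NULL, seed = 1L, keep_history = FALSE) {
  stopifnot(inherits(bounds, "vi_bounds"), inherits(config, "gpso_config"))
  d <- length(bounds)
  if (d < 1L) stop("bounds must have at least one dimension", call. = FALSE)
  fixed <- resolve_fixed(fixed, bounds)
  withr::with_seed(seed, {
    run_swarm(objective, bounds, config, fixed, transform, seed,
              keep_history, graded = TRUE)
  })
}

#' Classic PSO (reference implementation)
#'
#' The two-term velocity update
#' `v[t+1] = omega*v[t] + r1*c1*(pbest - x) + r2*c2*(gbest - x)` with a single
#' global leader.  Written against the same harness as [gpso_optimize()] so
#' the two consume the random stream identically; it serves as the reduction
#' oracle (single-group GPSO with tied leader draws and `c2' = c2 + c3` must
#' match it bit-for-bit).
#'
#' @inheritParams gpso_optimize
#' @return A `gpso_trace`.
#' @export
pso_optimize <- function(objective, bounds, config, fixed = NULL,
                         transform = NULL, seed = 1L, keep_history = FALSE) {
  stopifnot(inherits(bounds, "vi_bounds"), inherits(config, "gpso_config"))
  fixed <- resolve_fixed(fixed, bounds)
  withr::with_seed(seed, {
    run_swarm(objective, bounds, config, fixed, transform, seed,
              keep_history, graded = FALSE)
  })
}

# map a `fixed` spec (named by dimension name or index) to list(idx, values)
resolve_fixed <- function(fixed, bounds) {
  if (is.null(fixed) || length(fixed) == 0L) return(NULL)
  nm <- names(fixed)
  dn <- names(bounds$lower)
  if (is.null(nm)) stop("fixed must be a named vector", call. = FALSE)
  idx <- suppressWarnings(as.integer(nm))
  if (anyNA(idx)) {
    if (is.null(dn)) stop("fixed names do not match unnamed bounds", call. = FALSE)
    idx <- match(nm, dn)
    if (anyNA(idx)) {
      stop("fixed dimension(s) not found: ", paste(nm[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  }
  vals <- pmin(pmax(as.numeric(fixed), bounds$lower[idx]), bounds$upper[idx])
  list(idx = idx, values = vals)
}

pin_fixed <- function(X, fixed) {
  if (is.null(fixed)) return(X)
  X[, fixed$idx] <- matrix(fixed$values, nrow(X), length(fixed$idx), byrow = TRUE)
  X
}

# The three-term velocity rule.  The two leader terms are summed before
# being added to the rest so that, with tied draws and a single group, they
# collapse to the classic-PSO leader term exactly (bit-for-bit reduction).
gpso_velocity <- function(V, X, P, GB, UB, omega, c1, c2, c3, r1, r2, r3) {
  omega * V +
    (r1 * c1) * (P - X) +
    ((r2 * c2) * (GB - X) + (r3 * c3) * (UB - X))
}

# classic two-term rule (momentum variant)
pso_velocity <- function(V, X, P, GB, omega, c1, c2, r1, r2) {
  omega * V + (r1 * c1) * (P - X) + (r2 * c2) * (GB - X)
}

# shared swarm loop; `graded` switches between the Eq.-(4)-style three-term
# update (per-group leaders + universal leader) and the classic global-best
# update.  RNG consumption order is identical in both modes apart from the
# extra r3 draw, which `tie_leader_draws` removes.
run_swarm <- function(objective, bounds, config, fixed, transform, seed,
                      keep_history, graded) {
  n <- config$population
  d <- length(bounds)
  span <- bounds$upper - bounds$lower
  group <- if (graded) rep(seq_len(config$n_groups),
                           each = n / config$n_groups) else rep(1L, n)

  X <- matrix(stats::runif(n * d), n, d,
              dimnames = list(NULL, names(bounds$lower)))
  X <- sweep(sweep(X, 2, span, "*"), 2, bounds$lower, "+")
  X <- pin_fixed(X, fixed)
  if (!is.null(transform)) X <- pin_fixed(clamp(transform(X), bounds), fixed)
  V <- matrix(0, n, d)

  ev <- eval_swarm(objective, X)
  n_nonfinite <- ev$n_nonfinite
  P <- X                      # personal bests
  pf <- ev$f
  lead <- group_argbest(pf, group)          # one index per group
  u_lead <- lead[which.min(pf[lead])]       # universal leader (particle index)

  best <- numeric(config$max_iterations)
  why <- "iteration_cap"
  history <- if (keep_history) vector("list", config$max_iterations) else NULL
  iters <- 0L

  for (t in seq_len(config$max_iterations)) {
    GB <- P[lead[group], , drop = FALSE]             # group leader per particle
    UB <- matrix(P[u_lead, ], n, d, byrow = TRUE)    # universal leader

    r1 <- draw_r(n, d, config$r_mode)
    r2 <- draw_r(n, d, config$r_mode)
    if (graded) {
      r3 <- if (config$tie_leader_draws) r2 else draw_r(n, d, config$r_mode)
      V <- gpso_velocity(V, X, P, GB, UB, config$omega,
                         config$c1, config$c2, config$c3, r1, r2, r3)
    } else {
      V <- pso_velocity(V, X, P, UB, config$omega, config$c1, config$c2,
                        r1, r2)
    }
    if (!is.null(fixed)) V[, fixed$idx] <- 0
    X <- clamp(X + V, bounds)
    X <- pin_fixed(X, fixed)
    if (!is.null(transform)) X <- pin_fixed(clamp(transform(X), bounds), fixed)

    ev <- eval_swarm(objective, X)
    n_nonfinite <- n_nonfinite + ev$n_nonfinite
    imp <- ev$f < pf           # strict: earlier (lower-index) record survives ties
    if (any(imp)) {
      P[imp, ] <- X[imp, , drop = FALSE]
      pf[imp] <- ev$f[imp]
      lead <- group_argbest(pf, group)
      u_lead <- lead[which.min(pf[lead])]
    }

    iters <- t
    best[t] <- pf[u_lead]
    if (keep_history) history[[t]] <- X
    if (best[t] < config$tolerance) { why <- "tolerance"; break }
  }

  new_trace(best[seq_len(iters)], stats::setNames(P[u_lead, ], names(bounds$lower)),
            iters, why, seed, config,
            extra = list(n_nonfinite = n_nonfinite,
                         history = if (keep_history) history[seq_len(iters)] else NULL,
                         pbest_fitness = pf,
                         group = group))
}
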
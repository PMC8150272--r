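#' Inversion target
#'
#' The desired patient observations together with the inputs already known
#' for the patient (age and weight, which are fixed during the search — and
#' optionally any other setting dimension).
#'
#' @param observation Named 7-vector of target observations (all finite).
#' @param known_inputs Named numeric vector of fixed input dimensions,
#'   e.g. `c(age = 6, weight = 22)`.
#' @return Object of class `inversion_target`.
#' @export
inversion_target <- function(observation, known_inputs) {
  of <- vi_observation_fields()
  if (is.data.frame(observation)) observation <- unlist(observation[1, of])
  if (is.null(names(observation))) names(observation) <- of
  observation <- observation[of]
  if (anyNA(observation) || any(!is.finite(observation))) {
    stop("target observation must be finite in all 7 components", call. = FALSE)
  }
  bad <- setdiff(names(known_inputs), vi_setting_fields())
  if (length(bad)) {
    stop("known_inputs name(s) not setting fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(observation = observation,
                 known_inputs = known_inputs),
            class = "inversion_target")
}

#' Inversion fitness: half the sum of squared normalized residuals
#'
#' `MSE_n = 1/2 * sum_i (OutputN_i - TargetN_i)^2`, where both the surrogate
#' prediction and the target are normalized between the surrogate's output
#' limits.  All 7 outputs contribute.  Note the definition is half a *sum*,
#' not a mean — it is kept exactly as published.
#'
#' @param settings Named 8-vector (or matrix of rows) of candidate settings.
#' @param model A `surrogate_model`.
#' @param target An [inversion_target()].
#' @param warn Warn when the normalized target leaves `[0, 1]` (target
#'   outside the surrogate's training range); permitted but worth logging.
#' @return Non-negative fitness value(s).
#' @export
fitness <- function(settings, model, target, warn = TRUE) {
  stopifnot(inherits(model, "surrogate_model"),
            inherits(target, "inversion_target"))
  tn <- normalize(target$observation, model$output_bounds)
  if (warn && any(tn < 0 | tn > 1)) {
    warning("normalized target outside [0, 1] for: ",
            paste(names(tn)[tn < 0 | tn > 1], collapse = ", "),
            call. = FALSE)
  }
  S <- settings_matrix(settings)
  Yn <- surrogate_forward_norm(model, normalize(S, model$input_bounds))
  out <- 0.5 * rowSums(sweep(Yn, 2, tn, "-")^2)
  if (nrow(S) == 1L) out[[1L]] else out
}

# swarm objective bound to one (model, normalized target) pair
make_fitness_objective <- function(model, tn) {
  ib <- model$input_bounds
  force(tn)
  function(X) {
    Yn <- surrogate_forward_norm(model, normalize(X, ib))
    0.5 * rowSums(sweep(Yn, 2, tn, "-")^2)
  }
}

# position transform enforcing the physical identity PIP = SetP + PEEP
pip_projection <- function(bounds) {
  j <- match(c("SetP", "PIP", "PEEP"), names(bounds$lower))
  if (anyNA(j)) stop("bounds must be named with setting fields", call. = FALSE)
  function(X) {
    X[, j[2]] <- X[, j[1]] + X[, j[3]]
    X
  }
}

#' Run one inversion trial
#'
#' One GPSO run minimizing [fitness()] for a single surrogate, with the
#' target's known inputs frozen and every position clamped to `bounds`.
#'
#' @param target An [inversion_target()].
#' @param model A `surrogate_model`.
#' @param config A [gpso_config()].
#' @param bounds Settings-space [vi_bounds()] (named; normally the observed
#'   bounds of the training cohort).
#' @param seed Trial seed.
#' @param project_pip If `TRUE`, project `PIP = SetP + PEEP` after each
#'   clamping step, restricting the search to physically consistent
#'   pressures.  Off by default (the published protocol searches `PIP` as a
#'   free dimension).
#' @return List of class `trial_result`: `best_settings`, `best_fitness`,
#'   `trace`, `seed`.
#' @export
run_trial <- function(target, model, config, bounds, seed = 1L,
                      project_pip = FALSE) {
  stopifnot(inherits(target, "inversion_target"))
  tn <- normalize(target$observation, model$output_bounds)
  if (any(tn < 0 | tn > 1)) {
    warning("normalized target outside [0, 1] for: ",
            paste(names(tn)[tn < 0 | tn > 1], collapse = ", "),
            call. = FALSE)
  }
  objective <- make_fitness_objective(model, tn)
  transform <- if (project_pip) pip_projection(bounds) else NULL
  trace <- gpso_optimize(objective, bounds, config,
                         fixed = target$known_inputs,
                         transform = transform, seed = seed)
  structure(list(best_settings = trace$final_best_position,
                 best_fitness = trace$final_best_fitness,
                 trace = trace, seed = seed),
            class = "trial_result")
}

#' Run an inversion campaign
#'
#' Repeats [run_trial()] `n_trials` times for every ensemble member, with
#' per-trial seeds derived deterministically from the campaign seed
#' (`seed + 1000 * network + trial`), then aggregates per-parameter
#' minimum / maximum / mean / standard deviation over all results pooled
#' across networks, identifies the overall best (lowest fitness), and keeps
#' the full trial table plus a per-network breakdown.
#'
#' @inheritParams run_trial
#' @param ensemble A `surrogate_ensemble` (or a list of `surrogate_model`s).
#' @param n_trials Trials per ensemble member.
#' @param seed Campaign seed.
#' @param top_k Results kept per trial (default 1: the swarm's universal
#'   best).
#' @return Object of class `inversion_report`: `stats` (per-parameter
#'   min/max/mean/sd data frame), `best_settings`, `best_fitness`, `trials`
#'   (one row per trial: network, trial, seed, fitness, 8 settings),
#'   `per_network` (same statistics within each network), `config` echo.
#' @export
run_campaign <- function(target, ensemble, config, bounds,
                         n_trials = 100L, seed = 1L, project_pip = FALSE,
                         top_k = 1L) {
  models <- if (inherits(ensemble, "surrogate_ensemble")) ensemble$models
            else ensemble
  if (length(models) == 0L || n_trials < 1L) {
    stop("need a non-empty ensemble and n_trials >= 1", call. = FALSE)
  }
  if (top_k != 1L) {
    stop("top_k > 1 is not implemented; each trial reports the universal best",
         call. = FALSE)
  }
  sf <- vi_setting_fields()
  rows <- vector("list", length(models) * n_trials)
  r <- 0L
  n_failed <- 0L
  for (m in seq_along(models)) {
    for (tr in seq_len(n_trials)) {
      trial_seed <- seed + 1000L * m + tr
      res <- tryCatch(
        run_trial(target, models[[m]], config, bounds,
                  seed = trial_seed, project_pip = project_pip),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("trial ", tr, " on network ", m, " failed: ",
                conditionMessage(res), call. = FALSE)
        n_failed <- n_failed + 1L
        next
      }
      r <- r + 1L
      rows[[r]] <- data.frame(network = m, trial = tr, seed = trial_seed,
                              fitness = res$best_fitness,
                              as.list(res$best_settings))
    }
  }
  if (r == 0L) stop("all trials failed", call. = FALSE)
  trials <- do.call(rbind, rows[seq_len(r)])

  stats <- aggregate_settings(trials[, sf, drop = FALSE])
  per_network <- lapply(split(trials, trials$network), function(d) {
    aggregate_settings(d[, sf, drop = FALSE])
  })
  ibest <- which.min(trials$fitness)
  structure(list(stats = stats,
                 best_settings = unlist(trials[ibest, sf]),
                 best_fitness = trials$fitness[ibest],
                 trials = trials,
                 per_network = per_network,
                 n_failed = n_failed,
                 target = target,
                 seed = seed,
                 n_trials = as.integer(n_trials),
                 n_networks = length(models),
                 project_pip = project_pip,
                 config = config),
            class = "inversion_report")
}

# pure aggregation used by reports (and re-checkable from the trial table)
aggregate_settings <- function(d) {
  data.frame(parameter = names(d),
             min = vapply(d, min, numeric(1)),
             max = vapply(d, max, numeric(1)),
             mean = vapply(d, mean, numeric(1)),
             sd = vapply(d, function(x) if (length(x) > 1) stats::sd(x) else 0,
                         numeric(1)),
             row.names = NULL)
}

#' @export
print.inversion_report <- function(x, ...) {
  cat("<inversion_report> ", nrow(x$trials), " trials (",
      x$n_networks, " networks x ", x$n_trials, "), best MSE_n ",
      format(x$best_fitness, digits = 5), "\n", sep = "")
  print(x$stats, digits = 4)
  invisible(x)
}

#' Write an inversion report to disk
#'
#' `report.json` (statistics, best settings, seeds, config) and
#' `trials.csv` (every trial best).  Output is deterministic: identical
#' campaigns yield byte-identical files.
#'
#' @param report An `inversion_report`.
#' @param dir Output directory (created if needed).
#' @param name Basename prefix for the two files.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, name = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  payload <- list(
    type = "ventinvert_inversion_report",
    target = as.list(report$target$observation),
    known_inputs = as.list(report$target$known_inputs),
    seed = report$seed,
    n_trials = report$n_trials,
    n_networks = report$n_networks,
    n_failed = report$n_failed,
    project_pip = report$project_pip,
    gpso = list(population = cfg$population, n_groups = cfg$n_groups,
                omega = cfg$omega, c1 = cfg$c1, c2 = cfg$c2, c3 = cfg$c3,
                max_iterations = cfg$max_iterations, tolerance = cfg$tolerance,
                r_mode = cfg$r_mode),
    best_fitness = report$best_fitness,
    best_settings = as.list(report$best_settings),
    stats = report$stats)
  jsonlite::write_json(payload, file.path(dir, paste0(name, ".json")),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  utils::write.csv(report$trials, file.path(dir, paste0(name, "_trials.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
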
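#' Pipeline configuration
#'
#' Bundles every stage's parameters behind three named profiles:
#'
#' * `"table2"` — the full-scale published protocol: 200 candidate networks
#'   with the top 10 kept, swarm population 2000 in 50 groups, 100 trials
#'   per network, termination at 100 iterations or fitness < 0.01.
#' * `"text"` — same scale with the long termination rule (1000 iterations
#'   or fitness < 1e-4).
#' * `"desk"` — everything scaled down about 10x (20 candidates / top 3,
#'   population 200 in 10 groups, 20 trials) so the whole flow runs on one
#'   CPU in minutes; used by the test-suite and acceptance script.
#'
#' @param profile One of `"desk"`, `"table2"`, `"text"`.
#' @param seed Global seed; every stage derives its own from it.
#' @param cohort A [cohort_spec()] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @param n_holdout Records reserved for inversion testing.
#' @param project_pip Passed to [run_campaign()].
#' @param ... Named overrides for individual fields (`n_candidates`, `k`,
#'   `population`, `n_groups`, `max_iterations`, `tolerance`, `n_trials`,
#'   `epochs`, `topology`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("desk", "table2", "text"),
                            seed = 1L, cohort = cohort_spec(),
                            n_holdout = 10L, project_pip = FALSE, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    desk   = list(n_candidates = 20L, k = 3L, population = 200L,
                  n_groups = 10L, max_iterations = 200L, tolerance = 1e-5,
                  n_trials = 20L, epochs = 2000L),
    table2 = list(n_candidates = 200L, k = 10L, population = 2000L,
                  n_groups = 50L, max_iterations = 100L, tolerance = 0.01,
                  n_trials = 100L, epochs = 2000L),
    text   = list(n_candidates = 200L, k = 10L, population = 2000L,
                  n_groups = 50L, max_iterations = 1000L, tolerance = 1e-4,
                  n_trials = 100L, epochs = 2000L))
  over <- list(...)
  base[names(over)] <- over
  cohort$seed <- as.integer(seed)
  if (base$k > base$n_candidates) {
    stop("ensemble size k exceeds n_candidates", call. = FALSE)
  }
  structure(c(list(profile = profile, seed = as.integer(seed),
                   cohort = cohort, n_holdout = as.integer(n_holdout),
                   project_pip = project_pip,
                   topology = if (is.null(over$topology)) c(8, 16, 14, 7)
                              else over$topology),
              base[setdiff(names(base), "topology")]),
            class = "pipeline_config")
}

pipeline_gpso_config <- function(config) {
  gpso_config(population = config$population, n_groups = config$n_groups,
              max_iterations = config$max_iterations,
              tolerance = config$tolerance)
}

#' Run the staged pipeline
#'
#' Executes simulate -> prune -> train -> invert -> report, each stage
#' reading and writing plain-text artifacts under `out`:
#'
#' * `cohort.csv`, `truth.csv`, `spec.json` (simulate)
#' * `pruned.csv`, `prune_report.json`, `segregation.json` (prune)
#' * `models/` with per-member archives + `ensemble.json` (train)
#' * `reports/case_##.json` / `_trials.csv`, one per held-out record (invert)
#' * `summary.json` (report)
#'
#' Stages are pure functions of (inputs, config, seed); with `resume = TRUE`
#' a stage whose outputs already exist is skipped, so a failed run can be
#' restarted.  `stages` restricts execution (e.g. `c("simulate", "prune")`).
#'
#' @param config A [pipeline_config()].
#' @param out Artifact directory.
#' @param stages Stage subset, in canonical order.
#' @param resume Skip stages whose outputs exist (default `TRUE`).
#' @param cohort_file Optional external cohort CSV; replaces the simulate
#'   stage (no truth table, so recovery diagnostics are omitted).
#' @param quiet Suppress progress messages.
#' @return Path `out`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out = "ventinvert_run",
                         stages = c("simulate", "prune", "train",
                                    "invert", "report"),
                         resume = TRUE, cohort_file = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[ventinvert] ", ...)
  p <- function(...) file.path(out, ...)

  if ("simulate" %in% stages) {
    if (!is.null(cohort_file)) {
      say("simulate: using external cohort ", cohort_file)
      file.copy(cohort_file, p("cohort.csv"), overwrite = TRUE)
    } else if (resume && file.exists(p("cohort.csv"))) {
      say("simulate: artifacts exist, skipping")
    } else {
      say("simulate: synthetic cohort (seed ", config$seed, ")")
      sim <- generate_cohort(config$cohort)
      write_cohort(sim$observed, p("cohort.csv"))
      write_cohort(sim$truth, p("truth.csv"))
      jsonlite::write_json(unclass(config$cohort), p("spec.json"),
                           digits = NA, auto_unbox = TRUE)
    }
  }

  if ("prune" %in% stages) {
    if (resume && file.exists(p("pruned.csv")) &&
        file.exists(p("segregation.json"))) {
      say("prune: artifacts exist, skipping")
    } else {
      cohort <- read_cohort(p("cohort.csv"))
      say("prune: ", nrow(cohort), " raw rows")
      pr <- prune_cohort(cohort, seed = config$seed + 100L)
      write_cohort(pr$records, p("pruned.csv"))
      jsonlite::write_json(
        list(n_original = pr$n_original,
             n_dropped_missing = pr$n_dropped_missing,
             n_dropped_unimputable = pr$n_dropped_unimputable,
             n_final = pr$n_final,
             imputed_cells = as.list(pr$imputed_cells),
             cdyn_derived = pr$cdyn_derived,
             cdyn_conflicts = pr$cdyn_conflicts,
             bounds = list(lower = as.list(pr$bounds$lower),
                           upper = as.list(pr$bounds$upper)),
             seed = pr$seed),
        p("prune_report.json"), digits = NA, auto_unbox = TRUE)
      plan <- segregate(pr$records, n_holdout = config$n_holdout,
                        seed = config$seed + 200L)
      jsonlite::write_json(
        list(train = plan$train, validation = plan$validation,
             test = plan$test, holdout = plan$holdout,
             counts = as.list(plan$counts), seed = plan$seed),
        p("segregation.json"), digits = NA, auto_unbox = TRUE)
      say("prune: ", pr$n_final, " complete rows; holdout ",
          length(plan$holdout))
    }
  }

  if ("train" %in% stages) {
    if (resume && file.exists(p("models", "ensemble.json"))) {
      say("train: artifacts exist, skipping")
    } else {
      pruned <- read_cohort(p("pruned.csv"))
      seg <- jsonlite::read_json(p("segregation.json"), simplifyVector = TRUE)
      modelling <- pruned[sort(c(seg$train, seg$validation, seg$test)), ]
      say("train: ", config$n_candidates, " candidates on ",
          nrow(modelling), " records, keeping top ", config$k)
      ens <- train_ensemble(modelling, n_candidates = config$n_candidates,
                            k = config$k, topology = config$topology,
                            seed = config$seed + 300L,
                            epochs = config$epochs)
      write_ensemble(ens, p("models"))
      say("train: total_error range ",
          paste(format(range(vapply(ens$models, `[[`, 1, "total_error")),
                       digits = 4), collapse = " .. "))
    }
  }

  if ("invert" %in% stages) {
    if (resume && file.exists(p("reports", "done"))) {
      say("invert: artifacts exist, skipping")
    } else {
      pruned <- read_cohort(p("pruned.csv"))
      seg <- jsonlite::read_json(p("segregation.json"), simplifyVector = TRUE)
      ens <- read_ensemble(p("models"))
      modelling <- pruned[sort(c(seg$train, seg$validation, seg$test)), ]
      bounds <- observed_bounds(modelling, vi_setting_fields())
      gcfg <- pipeline_gpso_config(config)
      dir.create(p("reports"), showWarnings = FALSE)
      for (i in seq_along(seg$holdout)) {
        row <- pruned[seg$holdout[i], ]
        tgt <- inversion_target(row[, vi_observation_fields()],
                                c(age = row$age, weight = row$weight))
        say("invert: case ", i, "/", length(seg$holdout))
        rep_i <- run_campaign(tgt, ens, gcfg, bounds,
                              n_trials = config$n_trials,
                              seed = config$seed + 10000L * i,
                              project_pip = config$project_pip)
        write_report(rep_i, p("reports"), sprintf("case_%02d", i))
      }
      writeLines(as.character(length(seg$holdout)), p("reports", "done"))
    }
  }

  if ("report" %in% stages) {
    files <- sort(list.files(p("reports"), pattern = "^case_\\d+\\.json$",
                             full.names = TRUE))
    cases <- lapply(files, jsonlite::read_json, simplifyVector = TRUE)
    jsonlite::write_json(
      list(profile = config$profile, seed = config$seed,
           n_cases = length(cases),
           best_fitness = vapply(cases, function(cc) cc$best_fitness,
                                 numeric(1)),
           cases = basename(files)),
      p("summary.json"), digits = NA, auto_unbox = TRUE)
    say("report: ", length(cases), " cases summarized")
  }

  invisible(out)
}
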
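# Shared fixtures, built once per test run and cached (all generated in
# code; nothing is read from disk).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

sphere <- function(X) rowSums(X^2)

# small cohort from the unhealthy stratum (the surrogate's inputs carry no
# lung-status information, so single-stratum data keep the forward map a
# true function; see the methods vignette)
desk_cohort <- function() {
  cached("desk_cohort", function() {
    generate_cohort(cohort_spec(n_patients = 20, records_per_patient = 20,
                                sigma = 0.02, missing_fraction = 0,
                                healthy_fraction = 0, seed = 11))
  })
}

# small trained ensemble on the desk cohort (3 of 5 candidates)
desk_ensemble <- function() {
  cached("desk_ensemble", function() {
    suppressWarnings(
      train_ensemble(desk_cohort()$observed, n_candidates = 5, k = 3,
                     seed = 42, epochs = 1200, patience = 1200))
  })
}

# single-layer (pure linear) surrogate with hand-set weights: full control,
# no training, unit output bounds so normalization is the identity
toy_linear_surrogate <- function(seed = 5) {
  withr::with_seed(seed, {
    W <- matrix(stats::runif(8 * 7, -0.1, 0.1), 8, 7)
    diag(W) <- 0.8          # dominant diagonal keeps the map invertible
    b <- stats::runif(7, -0.05, 0.05)
    ib <- vi_bounds(stats::setNames(rep(0, 8), vi_setting_fields()),
                    stats::setNames(rep(1, 8), vi_setting_fields()))
    ob <- vi_bounds(stats::setNames(rep(0, 7), vi_observation_fields()),
                    stats::setNames(rep(1, 7), vi_observation_fields()))
    structure(list(net = list(sizes = c(8L, 7L), W = list(W), b = list(b)),
                   topology = integer(0), input_bounds = ib,
                   output_bounds = ob, split_seed = seed,
                   split_sizes = c(0L, 0L, 0L),
                   errors = c(train = 0, validation = 0, test = 0),
                   total_error = 0),
              class = "surrogate_model")
  })
}

# complete random cohort rows on the canonical 15 columns (no model behind
# them; for data-prep bookkeeping tests)
random_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    b <- default_setting_bounds()
    S <- sapply(seq_along(b$lower), function(j) {
      stats::runif(n, b$lower[j], b$upper[j])
    })
    colnames(S) <- vi_setting_fields()
    O <- cbind(Vti = stats::runif(n, 20, 900), Cdyn = stats::runif(n, 2, 60),
               EtCO2 = stats::runif(n, 15, 70), SpO2 = stats::runif(n, 80, 100),
               HR = stats::runif(n, 50, 180), BP = stats::runif(n, 60, 110),
               Temp = stats::runif(n, 36, 40))
    data.frame(S, O)
  })
}
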
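#' Ground-truth ventilated-patient model
#'
#' A deterministic, smooth response map `g: settings -> observations` used to
#' generate synthetic cohorts with known answers.  It is not a mechanistic
#' lung simulator; its functional forms are chosen to be monotone where
#' physiology dictates and to make the inverse problem well-posed, so that
#' surrogate-training and parameter-recovery tests are meaningful:
#'
#' * `Cdyn` depends on weight (allometric), age (mild stiffening) and lung
#'   status (unhealthy lungs multiply compliance by `unhealthy_cdyn`), never
#'   on the ventilator settings.
#' * `Vti = Cdyn * (PIP - PEEP)` holds exactly (the dynamic-compliance
#'   identity, enforced to machine precision).
#' * `EtCO2` falls exponentially with specific minute ventilation
#'   `RR * Vti / weight`, bounded between hyper- and hypo-ventilation
#'   asymptotes and strictly monotone (no hard clipping).
#' * `SpO2` rises and saturates with FiO2 and PEEP (recruitment), with a
#'   larger shunt fraction for unhealthy lungs; clipped to \[0, 100\].
#' * `BP` falls with PEEP and SetP (raised intrathoracic pressure), `HR`
#'   rises with EtCO2 and falls with pressure support, `Temp` is nearly
#'   constant per patient.  These couplings are deliberately simple and
#'   bounded.
#'
#' All coefficients sit in one `params` block, documented here and
#' overridable, so the "stated world" is explicit.
#'
#' @param sigma Relative (multiplicative) observation-noise scale applied by
#'   [generate_cohort()]; 0 gives noiseless records.
#' @param bounds Settings box, default [default_setting_bounds()].
#' @param unhealthy_cdyn Compliance multiplier for unhealthy lungs.
#' @param params Optional named list overriding individual coefficients.
#' @return Object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(sigma = 0.02,
                               bounds = default_setting_bounds(),
                               unhealthy_cdyn = 0.45,
                               params = list()) {
  p <- list(
    cdyn_w_coef = 1.6, cdyn_w_exp = 0.9, cdyn_age_slope = 0.004,
    # EtCO2 falls exponentially with specific minute ventilation
    # RR*Vti/weight (mL/kg/min): bounded in (base, base+span), strictly
    # decreasing in RR and Vti, increasing in weight at fixed flow
    etco2_base = 10, etco2_span = 70, etco2_sv_scale = 220,
    # oxygenation improves over the whole clinical FiO2 titration range
    # (decay length 60 % FiO2), so saturation stays informative about FiO2
    spo2_shunt_healthy = 0.035, spo2_shunt_unhealthy = 0.18,
    spo2_fio2_scale = 60, spo2_peep_scale = 6,
    bp_base = 98, bp_peep_slope = 1.6, bp_setp_slope = 0.3, bp_unhealthy = 3,
    hr_base = 70, hr_etco2_slope = 0.9, hr_psv_slope = 2,
    hr_size_coef = 40, hr_size_scale = 8, hr_unhealthy = 4,
    temp_base = 38.6, temp_age_slope = 0.01, temp_w_slope = 0.004,
    temp_unhealthy = 0.3
  )
  p[names(params)] <- params
  structure(list(sigma = sigma, bounds = bounds,
                 unhealthy_cdyn = unhealthy_cdyn, params = p),
            class = "ground_truth_model")
}

#' Default settings bounds for the synthetic world
#'
#' Physiologically conventional box for small-animal pressure-controlled
#' ventilation: SetP 5-30 and PEEP 0-12 cmH2O (so PIP up to 42), pressure
#' support 0-15 cmH2O, 8-40 breaths/min, FiO2 21-100%, ages 0.5-15 years and
#' body weight 2-60 kg (cats through large dogs).
#'
#' @return A named [vi_bounds()] over the 8 setting dimensions.
#' @export
default_setting_bounds <- function() {
  vi_bounds(
    c(SetP = 5, PIP = 5, PEEP = 0, PSV = 0, RR = 8, FiO2 = 21,
      age = 0.5, weight = 2),
    c(SetP = 30, PIP = 42, PEEP = 12, PSV = 15, RR = 40, FiO2 = 100,
      age = 15, weight = 60)
  )
}

# true dynamic compliance: settings-independent patient property
cdyn_true <- function(age, weight, healthy, model) {
  p <- model$params
  mult <- ifelse(healthy, 1, model$unhealthy_cdyn)
  p$cdyn_w_coef * weight^p$cdyn_w_exp * mult * (1 - p$cdyn_age_slope * age)
}

#' Deterministic patient response
#'
#' Evaluates the ground-truth map for one or more settings rows.  Inputs may
#' be a named 8-vector, a matrix with the 8 canonical setting columns, or a
#' data frame.
#'
#' @param settings Settings (see [vi_setting_fields()] for names/units).
#' @param model A [ground_truth_model()].
#' @param healthy Logical (recycled): lung status per row.
#' @param check_bounds Error on out-of-box settings (default `TRUE`).
#' @return Data frame with the 7 observation columns.
#' @export
ground_truth_response <- function(settings, model, healthy = TRUE,
                                  check_bounds = TRUE) {
  stopifnot(inherits(model, "ground_truth_model"))
  S <- settings_matrix(settings)
  if (check_bounds) {
    lo <- model$bounds$lower[colnames(S)]
    hi <- model$bounds$upper[colnames(S)]
    viol <- sweep(S, 2, lo, "<") | sweep(S, 2, hi, ">")
    if (any(viol)) {
      stop("settings outside model bounds in column(s): ",
           paste(unique(colnames(S)[colSums(viol) > 0]), collapse = ", "),
           call. = FALSE)
    }
  }
  p <- model$params
  healthy <- rep_len(as.logical(healthy), nrow(S))

  cdyn <- cdyn_true(S[, "age"], S[, "weight"], healthy, model)
  vti <- cdyn * (S[, "PIP"] - S[, "PEEP"])

  sv <- S[, "RR"] * vti / S[, "weight"]
  etco2 <- p$etco2_base + p$etco2_span * exp(-sv / p$etco2_sv_scale)

  shunt <- ifelse(healthy, p$spo2_shunt_healthy, p$spo2_shunt_unhealthy)
  spo2 <- 100 * (1 - shunt * exp(-(S[, "FiO2"] - 21) / p$spo2_fio2_scale -
                                   S[, "PEEP"] / p$spo2_peep_scale))
  spo2 <- pmin(pmax(spo2, 0), 100)

  bp <- p$bp_base - p$bp_peep_slope * S[, "PEEP"] -
    p$bp_setp_slope * S[, "SetP"] - p$bp_unhealthy * (!healthy)

  hr <- p$hr_base + p$hr_etco2_slope * (etco2 - 35) -
    p$hr_psv_slope * S[, "PSV"] +
    p$hr_size_coef * exp(-S[, "weight"] / p$hr_size_scale) +
    p$hr_unhealthy * (!healthy)
  hr <- pmin(pmax(hr, 40), 220)

  temp <- p$temp_base - p$temp_age_slope * S[, "age"] +
    p$temp_w_slope * S[, "weight"] - p$temp_unhealthy * (!healthy)

  data.frame(Vti = vti, Cdyn = cdyn, EtCO2 = etco2, SpO2 = spo2,
             HR = hr, BP = bp, Temp = temp)
}

# coerce settings input to a matrix with canonical columns
settings_matrix <- function(settings) {
  sf <- vi_setting_fields()
  if (is.data.frame(settings)) {
    missing <- setdiff(sf, names(settings))
    if (length(missing)) {
      stop("settings missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    settings <- as.matrix(settings[, sf, drop = FALSE])
  }
  if (!is.matrix(settings)) {
    if (is.null(names(settings))) names(settings) <- sf
    missing <- setdiff(sf, names(settings))
    if (length(missing)) {
      stop("settings missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    settings <- matrix(settings[sf], 1L, dimnames = list(NULL, sf))
  }
  missing <- setdiff(sf, colnames(settings))
  if (length(missing)) {
    stop("settings missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- settings[, sf, drop = FALSE]
  if (anyNA(out) || any(!is.finite(out))) {
    stop("settings must be finite", call. = FALSE)
  }
  out
}

#' Synthetic cohort specification
#'
#' Defaults emulate the scale of the clinical cohort the pipeline was
#' designed around: 24 patients (a quarter feline), 6 of them with healthy
#' lungs, about 30 timestamped records each, 2% relative observation noise,
#' and 15% of maskable cells missing (demographics are always recorded, so
#' age and weight are never masked).
#'
#' @param n_patients,records_per_patient Cohort size.
#' @param missing_fraction Fraction of maskable cells set to `NA` in the
#'   observable table.  Only the 7 observation fields are maskable: settings
#'   come from the ventilator log and are always recorded, whereas patient
#'   observations are charted sporadically; demographics are likewise always
#'   known.
#' @param sigma Relative observation noise passed to the model.
#' @param healthy_fraction Fraction of patients with healthy lungs.
#' @param feline_fraction Fraction of patients that are cats (smaller body
#'   weights).
#' @param seed RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 24L, records_per_patient = 30L,
                        missing_fraction = 0.15, sigma = 0.02,
                        healthy_fraction = 6 / 24, feline_fraction = 4 / 24,
                        seed = 1L) {
  stopifnot(n_patients >= 1, records_per_patient >= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            sigma >= 0, healthy_fraction >= 0, healthy_fraction <= 1,
            feline_fraction >= 0, feline_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 records_per_patient = as.integer(records_per_patient),
                 missing_fraction = missing_fraction, sigma = sigma,
                 healthy_fraction = healthy_fraction,
                 feline_fraction = feline_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic ventilated-patient cohort
#'
#' Samples per-patient demographics and lung status, samples settings
#' uniformly in the box with the physical identity `PIP = SetP + PEEP`
#' enforced, evaluates the ground-truth response, applies multiplicative
#' noise `obs * (1 + sigma * eps)` with standard-normal `eps` (SpO2 re-clipped
#' to \[0, 100\]), and masks observation cells completely at random at the
#' requested fraction.  Settings and demographics are never masked (they are
#' machine-logged / known).
#'
#' @param spec A [cohort_spec()].
#' @param model A [ground_truth_model()]; its `sigma` is overridden by the
#'   spec's.
#' @return List with `observed` (the cohort as an analyst would see it:
#'   `patient_id`, `species`, `lung_status`, 15 canonical columns, `NA`s for
#'   masked cells), `truth` (same rows, noiseless and complete; never fed to
#'   training), `model` and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            model = ground_truth_model(sigma = spec$sigma)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "ground_truth_model"))
  withr::with_seed(spec$seed, {
    np <- spec$n_patients
    n_healthy <- round(spec$healthy_fraction * np)
    n_feline <- round(spec$feline_fraction * np)
    healthy <- seq_len(np) <= n_healthy      # deterministic counts, shuffled
    healthy <- sample(healthy)
    feline <- sample(seq_len(np) <= n_feline)
    age <- stats::runif(np, 0.5, 15)
    weight <- ifelse(feline, stats::runif(np, 2.5, 6), stats::runif(np, 5, 60))

    n <- np * spec$records_per_patient
    pid <- rep(seq_len(np), each = spec$records_per_patient)
    b <- model$bounds
    setp <- stats::runif(n, b$lower["SetP"], 30)
    peep <- stats::runif(n, b$lower["PEEP"], b$upper["PEEP"])
    S <- cbind(SetP = setp, PIP = setp + peep, PEEP = peep,
               PSV = stats::runif(n, b$lower["PSV"], b$upper["PSV"]),
               RR = stats::runif(n, b$lower["RR"], b$upper["RR"]),
               FiO2 = stats::runif(n, b$lower["FiO2"], b$upper["FiO2"]),
               age = age[pid], weight = weight[pid])
    obs_true <- ground_truth_response(S, model, healthy = healthy[pid])

    truth <- data.frame(patient_id = pid,
                        species = ifelse(feline[pid], "feline", "canine"),
                        lung_status = ifelse(healthy[pid], "healthy", "unhealthy"),
                        S, obs_true)

    obs <- obs_true
    if (spec$sigma > 0) {
      eps <- matrix(stats::rnorm(n * ncol(obs)), n, ncol(obs))
      obs <- obs * (1 + spec$sigma * eps)
      obs$SpO2 <- pmin(pmax(obs$SpO2, 0), 100)
    }
    observed <- data.frame(patient_id = pid,
                           species = truth$species,
                           lung_status = truth$lung_status,
                           S, obs)

    maskable <- vi_observation_fields()
    if (spec$missing_fraction > 0) {
      n_cells <- n * length(maskable)
      n_mask <- round(spec$missing_fraction * n_cells)
      cells <- sample.int(n_cells, n_mask)
      row_i <- ((cells - 1L) %% n) + 1L
      col_i <- ((cells - 1L) %/% n) + 1L
      for (j in seq_along(maskable)) {
        hit <- row_i[col_i == j]
        if (length(hit)) observed[hit, maskable[j]] <- NA_real_
      }
    }
    list(observed = observed, truth = truth, model = model, spec = spec)
  })
}

#' One inversion test case with a known answer
#'
#' Samples a patient and a settings vector from the central 70% of each
#' bound range (quantiles 0.15-0.85, avoiding the saturating edges of the
#' response map, e.g. the flat SpO2 plateau at very high FiO2, where no
#' method could identify the setting), with `PIP = SetP + PEEP`, and returns
#' the noiseless response as the inversion target.
#'
#' @param model A [ground_truth_model()].
#' @param seed RNG seed (same seed, same fixture).
#' @param healthy Lung status of the simulated patient.
#' @return List: `settings` (named 8-vector, the correct answer `s*`),
#'   `target` (named 7-vector `g(s*)`), `known_inputs` (`age`, `weight`) and
#'   `healthy`.
#' @export
make_inversion_fixture <- function(model = ground_truth_model(), seed = 1L,
                                   healthy = FALSE) {
  stopifnot(inherits(model, "ground_truth_model"))
  withr::with_seed(seed, {
    b <- model$bounds
    q <- stats::runif(8, 0.15, 0.85)
    s <- b$lower + q * (b$upper - b$lower)
    names(s) <- names(b$lower)
    s["PEEP"] <- min(s["PEEP"], b$upper["PEEP"])
    s["PIP"] <- s["SetP"] + s["PEEP"]
    obs <- ground_truth_response(s, model, healthy = healthy)
    list(settings = s,
         target = stats::setNames(as.numeric(obs[1, ]), names(obs)),
         known_inputs = c(age = unname(s["age"]), weight = unname(s["weight"])),
         healthy = healthy)
  })
}
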
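#' Canonical cohort fields
#'
#' A cohort record holds 8 input fields (6 ventilator settings plus two
#' demographics) and 7 patient-response fields.  All functions in the package
#' address columns by these names and in this order.
#'
#' Settings: `SetP` (set inspiratory pressure above PEEP, cmH2O), `PIP` (peak
#' inspiratory pressure, cmH2O), `PEEP` (positive end-expiratory pressure,
#' cmH2O), `PSV` (pressure-support level, cmH2O), `RR` (mandatory respiratory
#' rate, breaths/min), `FiO2` (inspired oxygen fraction, %), `age` (years),
#' `weight` (kg).
#'
#' Observations: `Vti` (inspiratory tidal volume, mL), `Cdyn` (dynamic
#' compliance, mL/cmH2O), `EtCO2` (end-tidal CO2, mmHg), `SpO2` (peripheral
#' oxygen saturation, %), `HR` (heart rate, beats/min), `BP` (mean arterial
#' pressure, mmHg), `Temp` (body temperature, degrees C).
#'
#' @return Character vector of column names.
#' @export
vi_setting_fields <- function() {
  c("SetP", "PIP", "PEEP", "PSV", "RR", "FiO2", "age", "weight")
}

#' @rdname vi_setting_fields
#' @export
vi_observation_fields <- function() {
  c("Vti", "Cdyn", "EtCO2", "SpO2", "HR", "BP", "Temp")
}

#' @rdname vi_setting_fields
#' @export
vi_fields <- function() c(vi_setting_fields(), vi_observation_fields())

#' Per-dimension box bounds
#'
#' Container for lower/upper limits of a search box or a normalization range.
#' Dimensions are named when `lower` is named.
#'
#' @param lower,upper Numeric vectors of equal length with
#'   `lower[d] <= upper[d]` for every dimension `d`.
#' @return An object of class `vi_bounds` with elements `lower` and `upper`.
#' @examples
#' b <- vi_bounds(c(0, 0), c(1, 10))
#' @export
vi_bounds <- function(lower, upper) {
  lower <- as.numeric2(lower)
  upper <- as.numeric2(upper)
  if (length(lower) != length(upper)) {
    stop("bounds: lower and upper must have the same length", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds: limits must be finite", call. = FALSE)
  }
  if (any(lower > upper)) {
    stop("bounds: lower[d] > upper[d] for some dimension", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "vi_bounds")
}

# keep names while coercing
as.numeric2 <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' @export
print.vi_bounds <- function(x, ...) {
  nm <- names(x$lower)
  if (is.null(nm)) nm <- paste0("dim", seq_along(x$lower))
  cat("<vi_bounds> ", length(x$lower), " dimensions\n", sep = "")
  print(data.frame(lower = x$lower, upper = x$upper, row.names = nm))
  invisible(x)
}

#' @export
length.vi_bounds <- function(x) length(x$lower)

#' Bounds observed in a data frame
#'
#' Computes per-column min/max over non-missing cells, the convention used
#' both for truncating imputed values and for min-max normalization of
#' network inputs/outputs.
#'
#' @param df Data frame.
#' @param fields Columns to use (default: all canonical fields present).
#' @return A [vi_bounds()] with named dimensions.
#' @export
observed_bounds <- function(df, fields = intersect(vi_fields(), names(df))) {
  lo <- vapply(fields, function(f) suppressWarnings(min(df[[f]], na.rm = TRUE)),
               numeric(1))
  hi <- vapply(fields, function(f) suppressWarnings(max(df[[f]], na.rm = TRUE)),
               numeric(1))
  bad <- !is.finite(lo) | !is.finite(hi)
  if (any(bad)) {
    stop("observed_bounds: no observed values for field(s): ",
         paste(fields[bad], collapse = ", "), call. = FALSE)
  }
  vi_bounds(lo, hi)
}

#' Min-max normalization between declared limits
#'
#' Maps each component to `(x - lower) / (upper - lower)`.  A degenerate
#' feature (`lower == upper`) maps to 0.5 by convention so that constant
#' columns carry no gradient.  Out-of-bounds inputs yield values outside
#' \[0, 1\]; this is permitted (clamping is the caller's decision).
#'
#' @param x Numeric vector or matrix (columns = features).
#' @param bounds A [vi_bounds()] matching the feature count.
#' @return Same shape as `x`, on the unit scale.
#' @export
normalize <- function(x, bounds) {
  rng <- bounds$upper - bounds$lower
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(bounds))
    out <- sweep(x, 2, bounds$lower, "-")
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    if (any(rng == 0)) out[, rng == 0] <- 0.5
    out
  } else {
    stopifnot(length(x) == length(bounds) || length(bounds) == 1L)
    out <- (x - bounds$lower) / ifelse(rng > 0, rng, 1)
    if (length(bounds) == 1L) { if (rng == 0) out[] <- 0.5 } else out[rng == 0] <- 0.5
    out
  }
}

#' @rdname normalize
#' @export
denormalize <- function(x, bounds) {
  rng <- bounds$upper - bounds$lower
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(bounds))
    out <- sweep(x, 2, rng, "*")
    sweep(out, 2, bounds$lower, "+")
  } else {
    stopifnot(length(x) == length(bounds) || length(bounds) == 1L)
    x * rng + bounds$lower
  }
}

#' Clamp values to bounds
#'
#' Component-wise truncation to the nearest limit, the rule applied to every
#' particle position after each iteration and to every imputed cell.
#'
#' @inheritParams normalize
#' @return Same shape as `x`, with every component inside the box.
#' @export
clamp <- function(x, bounds) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(bounds))
    lo <- matrix(bounds$lower, nrow(x), ncol(x), byrow = TRUE)
    hi <- matrix(bounds$upper, nrow(x), ncol(x), byrow = TRUE)
    pmin(pmax(x, lo), hi)
  } else {
    stopifnot(length(x) == length(bounds) || length(bounds) == 1L)
    pmin(pmax(x, bounds$lower), bounds$upper)
  }
}
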
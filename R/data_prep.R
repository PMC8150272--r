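#' Dynamic compliance from the pressure swing
#'
#' `Cdyn = Vti / (PIP - PEEP)` — tidal volume delivered per unit of driving
#' pressure, the standard bedside measure of lung distensibility.
#'
#' @param vti Inspiratory tidal volume (mL).
#' @param pip Peak inspiratory pressure (cmH2O).
#' @param peep Positive end-expiratory pressure (cmH2O); must satisfy
#'   `pip > peep` elementwise.
#' @return Dynamic compliance (mL/cmH2O), vectorized.
#' @examples
#' compute_cdyn(300, 15, 5)  # 30 mL/cmH2O
#' @export
compute_cdyn <- function(vti, pip, peep) {
  if (any(pip <= peep, na.rm = TRUE)) {
    stop("compute_cdyn: PIP must exceed PEEP (compliance undefined)",
         call. = FALSE)
  }
  vti / (pip - peep)
}

#' Impute one field with a regression network
#'
#' Trains a small feed-forward network predicting `target_field` from the
#' other 14 canonical fields and fills its missing cells.  Training rows are
#' those where the target is observed; missing predictor cells (during both
#' training and prediction) are filled with the column mean of observed
#' values, so the imputer degrades gracefully as overall missingness grows
#' instead of requiring fully complete records.  Every imputed value is
#' truncated to the field's observed bounds.
#'
#' @param records Data frame containing the 15 canonical columns.
#' @param target_field Field to fill.
#' @param bounds A [vi_bounds()] over the 15 fields (observed, pre-imputation
#'   bounds); used for normalization and truncation.
#' @param seed RNG seed for the network initialization.
#' @param hidden Hidden-layer widths of the imputer network.
#' @param epochs,lr Training length and Adam learning rate.
#' @param min_train Minimum usable training rows; below this the field is
#'   declared un-imputable (an error condition handled by [prune_cohort()]).
#' @return List: `records` (target column filled), `n_imputed`, `model`.
#' @export
impute_field <- function(records, target_field, bounds, seed = 1L,
                         hidden = c(12, 8), epochs = 800L, lr = 0.02,
                         min_train = 25L) {
  fields <- vi_fields()
  stopifnot(target_field %in% fields, all(fields %in% names(records)))
  predictors <- setdiff(fields, target_field)
  miss <- is.na(records[[target_field]])
  if (!any(miss)) {
    return(list(records = records, n_imputed = 0L, model = NULL))
  }
  train_rows <- which(!miss)
  if (length(train_rows) < min_train) {
    stop("impute_field: only ", length(train_rows), " rows observe '",
         target_field, "' (need >= ", min_train, ")", call. = FALSE)
  }
  pb <- vi_bounds(bounds$lower[predictors], bounds$upper[predictors])
  tb <- vi_bounds(bounds$lower[target_field], bounds$upper[target_field])

  X <- as.matrix(records[, predictors])
  col_means <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- col_means[j]
  Xn <- normalize(X, pb)
  yn <- normalize(records[[target_field]][train_rows], tb)

  net <- withr::with_seed(seed, {
    mlp_train(Xn[train_rows, , drop = FALSE], matrix(yn, ncol = 1),
              hidden = hidden, epochs = epochs, lr = lr, patience = epochs)
  })
  pred <- denormalize(as.numeric(mlp_forward(net, Xn[miss, , drop = FALSE])), tb)
  records[[target_field]][miss] <- clamp(pred, tb)  # truncate to observed range
  list(records = records, n_imputed = sum(miss), model = net)
}

#' Pruning policy
#'
#' @param max_missing Rows missing strictly more than this many of the 15
#'   canonical fields are dropped before imputation (default: half, i.e. 7).
#' @param cdyn_conflict_tol Relative tolerance before a recorded `Cdyn` is
#'   flagged as conflicting with `Vti/(PIP-PEEP)`; the recorded value always
#'   wins (observational data is authoritative), conflicts are only counted.
#' @param min_train,hidden,epochs,lr Imputer settings, see [impute_field()].
#' @return List of class `prune_policy`.
#' @export
prune_policy <- function(max_missing = 7L, cdyn_conflict_tol = 0.05,
                         min_train = 25L, hidden = c(12, 8),
                         epochs = 800L, lr = 0.02) {
  structure(list(max_missing = as.integer(max_missing),
                 cdyn_conflict_tol = cdyn_conflict_tol,
                 min_train = as.integer(min_train), hidden = hidden,
                 epochs = as.integer(epochs), lr = lr),
            class = "prune_policy")
}

#' Prune a raw cohort: drop, derive, impute
#'
#' The pipeline that turns sporadically recorded clinical rows into a
#' complete modelling cohort:
#'
#' 1. drop rows missing more than `max_missing` of the 15 fields (counted);
#' 2. compute per-field observed bounds from the initial (pre-imputation)
#'    data — these bounds also truncate every later imputed value;
#' 3. where `Vti`, `PIP`, `PEEP` are present, fill a missing `Cdyn` directly
#'    from the compliance identity (and count, but keep, recorded values
#'    conflicting with it by more than the policy tolerance);
#' 4. impute the remaining incomplete fields, most-complete field first,
#'    each with its own regression network ([impute_field()]), clamping to
#'    the bounds of step 2;
#' 5. drop any rows still incomplete (only possible when a field was
#'    un-imputable) and report every count.
#'
#' @param records Data frame with the 15 canonical columns (extra columns
#'   such as `patient_id` pass through untouched).
#' @param policy A [prune_policy()].
#' @param seed Seed for the imputer networks.
#' @return List of class `prune_report`: `records` (complete cohort),
#'   `bounds`, and counts (`n_original`, `n_dropped_missing`,
#'   `n_dropped_unimputable`, `n_final`, `imputed_cells` per field,
#'   `cdyn_derived`, `cdyn_conflicts`, `unimputable_fields`).
#' @export
prune_cohort <- function(records, policy = prune_policy(), seed = 1L) {
  fields <- vi_fields()
  stopifnot(all(fields %in% names(records)))
  n_original <- nrow(records)

  n_miss_row <- rowSums(is.na(records[, fields]))
  keep <- n_miss_row <= policy$max_missing
  n_dropped_missing <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  bounds <- observed_bounds(records, fields)   # pre-imputation observed range

  # derive Cdyn from the identity where possible; recorded values win
  have3 <- !is.na(records$Vti) & !is.na(records$PIP) & !is.na(records$PEEP) &
    records$PIP > records$PEEP
  ident <- rep(NA_real_, nrow(records))
  ident[have3] <- records$Vti[have3] / (records$PIP[have3] - records$PEEP[have3])
  fill <- have3 & is.na(records$Cdyn)
  conflict <- have3 & !is.na(records$Cdyn) &
    abs(records$Cdyn - ident) > policy$cdyn_conflict_tol * pmax(abs(ident), 1e-12)
  records$Cdyn[fill] <- clamp(ident[fill],
                              vi_bounds(bounds$lower["Cdyn"], bounds$upper["Cdyn"]))
  cdyn_derived <- sum(fill)
  cdyn_conflicts <- sum(conflict)

  # impute most-complete field first
  completeness <- colSums(!is.na(records[, fields]))
  order_fields <- fields[order(-completeness)]
  imputed_cells <- stats::setNames(integer(length(fields)), fields)
  unimputable <- character(0)
  for (k in seq_along(order_fields)) {
    f <- order_fields[k]
    if (!anyNA(records[[f]])) next
    res <- tryCatch(
      impute_field(records, f, bounds, seed = seed + k,
                   hidden = policy$hidden, epochs = policy$epochs,
                   lr = policy$lr, min_train = policy$min_train),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("field '", f, "' un-imputable: ", conditionMessage(res),
              call. = FALSE)
      unimputable <- c(unimputable, f)
    } else {
      records <- res$records
      imputed_cells[f] <- res$n_imputed
    }
  }

  still <- rowSums(is.na(records[, fields])) > 0
  n_dropped_unimputable <- sum(still)
  records <- records[!still, , drop = FALSE]
  rownames(records) <- NULL

  structure(list(records = records, bounds = bounds,
                 n_original = n_original,
                 n_dropped_missing = n_dropped_missing,
                 n_dropped_unimputable = n_dropped_unimputable,
                 n_final = nrow(records),
                 imputed_cells = imputed_cells,
                 cdyn_derived = cdyn_derived,
                 cdyn_conflicts = cdyn_conflicts,
                 unimputable_fields = unimputable,
                 seed = seed),
            class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat("<prune_report> ", x$n_original, " rows -> ", x$n_final,
      " complete (", x$n_dropped_missing, " dropped too-sparse, ",
      x$n_dropped_unimputable, " dropped un-imputable)\n",
      "  imputed cells: ", sum(x$imputed_cells),
      " | Cdyn derived: ", x$cdyn_derived,
      " | Cdyn conflicts: ", x$cdyn_conflicts, "\n", sep = "")
  invisible(x)
}

#' Segregate a pruned cohort
#'
#' Uniformly samples `n_holdout` rows for inverse-mapping tests, then splits
#' the remainder into train/validation/test by `fractions`.  Selection is
#' completely random given the seed; the four index sets are disjoint and
#' exhaust the cohort.
#'
#' @param records Complete (pruned) cohort.
#' @param fractions Length-3 train/validation/test fractions summing to 1.
#' @param n_holdout Rows reserved for inversion testing.
#' @param seed RNG seed.
#' @return List of class `segregation_plan` with index vectors `train`,
#'   `validation`, `test`, `holdout` and a `counts` summary.
#' @export
segregate <- function(records, fractions = c(0.70, 0.15, 0.15),
                      n_holdout = 10L, seed = 1L) {
  n <- nrow(records)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  }
  if (n_holdout >= n) stop("n_holdout must be smaller than the cohort", call. = FALSE)
  withr::with_seed(seed, {
    holdout <- sort(sample.int(n, n_holdout))
    rest <- setdiff(seq_len(n), holdout)
    rest <- sample(rest)
    n_train <- round(fractions[1] * length(rest))
    n_val <- round(fractions[2] * length(rest))
    n_val <- min(n_val, length(rest) - n_train)
    train <- sort(rest[seq_len(n_train)])
    validation <- sort(rest[n_train + seq_len(n_val)])
    test <- sort(rest[-seq_len(n_train + n_val)])
    structure(list(train = train, validation = validation, test = test,
                   holdout = holdout,
                   counts = c(train = length(train),
                              validation = length(validation),
                              test = length(test), holdout = length(holdout)),
                   seed = seed, fractions = fractions),
              class = "segregation_plan")
  })
}

#' Cohort CSV input/output
#'
#' Plain-delimited text with the 15 canonical columns (missing cells empty);
#' extra columns (`patient_id`, `species`, `lung_status`) are preserved.
#'
#' @param path File path.
#' @param records Data frame to write.
#' @return `read_cohort` returns a data frame; `write_cohort` its path,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(vi_fields(), names(df))
  if (length(missing)) {
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
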
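#' Train one forward surrogate network
#'
#' Fits a feed-forward regression network mapping the 8 settings/demographic
#' inputs to the 7 patient responses.  Inputs and outputs are min-max
#' normalized to the cohort's observed bounds; hidden layers use tanh units
#' with a linear 7-unit output layer; training is full-batch Adam with early
#' stopping on the validation partition.  The per-model `total_error` is the
#' sum of squared prediction errors, on the normalized scale, over the
#' train + validation + test partitions together — the quantity the ensemble
#' selection ranks by.
#'
#' @param cohort Complete data frame with the 15 canonical columns.
#' @param topology Hidden-layer widths; the default `c(8, 16, 14, 7)` is the
#'   four-internal-layer configuration the pipeline was tuned with.
#' @param split_fractions Train/validation/test fractions (sum to 1); the
#'   split is re-randomized per network from `seed`.
#' @param seed RNG seed controlling split and initialization; identical seed,
#'   identical model.
#' @param epochs,lr,patience Trainer settings (see package vignette).
#' @param input_bounds,output_bounds Normalization bounds; default: observed
#'   bounds of `cohort`.  Pass cohort-wide bounds explicitly when training
#'   many networks so all share one scale.
#' @return Object of class `surrogate_model`: the network, its bounds,
#'   `total_error`, per-partition errors and the seed.
#' @export
train_network <- function(cohort, topology = c(8, 16, 14, 7),
                          split_fractions = c(0.70, 0.15, 0.15),
                          seed = 1L, epochs = 2000L, lr = 0.01,
                          patience = 200L,
                          input_bounds = NULL, output_bounds = NULL) {
  sf <- vi_setting_fields(); of <- vi_observation_fields()
  stopifnot(all(c(sf, of) %in% names(cohort)))
  if (nrow(cohort) < 20L) stop("cohort too small (< 20 records)", call. = FALSE)
  if (anyNA(cohort[, c(sf, of)])) {
    stop("cohort contains missing cells; run prune_cohort() first", call. = FALSE)
  }
  if (is.null(input_bounds)) input_bounds <- observed_bounds(cohort, sf)
  if (is.null(output_bounds)) output_bounds <- observed_bounds(cohort, of)

  Xn <- normalize(as.matrix(cohort[, sf]), input_bounds)
  Yn <- normalize(as.matrix(cohort[, of]), output_bounds)

  withr::with_seed(seed, {
    n <- nrow(Xn)
    idx <- sample.int(n)
    n_tr <- round(split_fractions[1] * n)
    n_va <- min(round(split_fractions[2] * n), n - n_tr - 1L)
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
    te <- idx[-seq_len(n_tr + n_va)]
    net <- mlp_train(Xn[tr, , drop = FALSE], Yn[tr, , drop = FALSE],
                     Xn[va, , drop = FALSE], Yn[va, , drop = FALSE],
                     hidden = topology, epochs = epochs, lr = lr,
                     patience = patience)
    errors <- c(train = mlp_sse(net, Xn[tr, , drop = FALSE], Yn[tr, , drop = FALSE]),
                validation = mlp_sse(net, Xn[va, , drop = FALSE], Yn[va, , drop = FALSE]),
                test = mlp_sse(net, Xn[te, , drop = FALSE], Yn[te, , drop = FALSE]))
    structure(list(net = net, topology = topology,
                   input_bounds = input_bounds, output_bounds = output_bounds,
                   split_seed = seed, split_sizes = c(length(tr), length(va), length(te)),
                   errors = errors, total_error = sum(errors)),
              class = "surrogate_model")
  })
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("<surrogate_model> 8 -> [", paste(x$topology, collapse = ", "),
      "] -> 7 | total_error ", format(x$total_error, digits = 5),
      " (seed ", x$split_seed, ")\n", sep = "")
  invisible(x)
}

#' Predict patient responses from a surrogate
#'
#' @param object A `surrogate_model`.
#' @param settings Named 8-vector, matrix or data frame of settings.
#' @param ... Unused.
#' @return Data frame with the 7 observation columns (denormalized units).
#' @export
predict.surrogate_model <- function(object, settings, ...) {
  S <- settings_matrix(settings)
  Yn <- surrogate_forward_norm(object, normalize(S, object$input_bounds))
  out <- denormalize(Yn, object$output_bounds)
  colnames(out) <- vi_observation_fields()
  as.data.frame(out)
}

# normalized-in, normalized-out forward pass on a swarm-sized matrix
surrogate_forward_norm <- function(model, Xn) mlp_forward(model$net, Xn)

#' Train candidates and keep the best
#'
#' Trains `n_candidates` networks, each with an independently randomized
#' split and initialization (derived seeds), and returns the `k` with the
#' smallest total error, in ascending order, together with the full error
#' list.  Individual training failures are skipped with a warning; fewer
#' than `k` successes is an error.
#'
#' @inheritParams train_network
#' @param n_candidates Networks to train.
#' @param k Ensemble size to keep.
#' @return Object of class `surrogate_ensemble`: `models` (length `k`,
#'   errors ascending), `all_errors` (length `n_candidates`, `NA` for
#'   failures), `k`, `seed`.
#' @export
train_ensemble <- function(cohort, n_candidates = 200L, k = 10L,
                           topology = c(8, 16, 14, 7),
                           split_fractions = c(0.70, 0.15, 0.15),
                           seed = 1L, epochs = 2000L, lr = 0.01,
                           patience = 200L) {
  if (k < 1L || n_candidates < k) {
    stop("need n_candidates >= k >= 1", call. = FALSE)
  }
  sf <- vi_setting_fields(); of <- vi_observation_fields()
  input_bounds <- observed_bounds(cohort, sf)
  output_bounds <- observed_bounds(cohort, of)
  models <- vector("list", n_candidates)
  errs <- rep(NA_real_, n_candidates)
  for (j in seq_len(n_candidates)) {
    m <- tryCatch(
      train_network(cohort, topology, split_fractions, seed = seed + j,
                    epochs = epochs, lr = lr, patience = patience,
                    input_bounds = input_bounds, output_bounds = output_bounds),
      error = function(e) e)
    if (inherits(m, "error")) {
      warning("candidate ", j, " failed: ", conditionMessage(m), call. = FALSE)
    } else {
      models[[j]] <- m
      errs[j] <- m$total_error
    }
  }
  ok <- which(!is.na(errs))
  if (length(ok) < k) stop("fewer than k networks trained successfully", call. = FALSE)
  top <- ok[order(errs[ok])][seq_len(k)]
  structure(list(models = models[top], all_errors = errs, k = k, seed = seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  sel <- vapply(x$models, function(m) m$total_error, numeric(1))
  cat("<surrogate_ensemble> top ", x$k, " of ",
      length(x$all_errors), " candidates | total_error ",
      format(min(sel), digits = 4), " .. ", format(max(sel), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Surrogate persistence (portable JSON)
#'
#' Self-describing plain-text archives: topology, weights, normalization
#' bounds, seed and errors.  `write_ensemble` stores one file per member
#' plus an `ensemble.json` manifest in `dir`.
#'
#' @param model,ensemble Objects to store.
#' @param path,dir Destination.
#' @return Readers return the restored object; writers their path, invisibly.
#' @export
write_surrogate <- function(model, path) {
  payload <- list(
    type = "ventinvert_surrogate", version = 1L,
    topology = model$topology,
    sizes = model$net$sizes,
    W = lapply(model$net$W, function(w) unclass(w)),
    b = model$net$b,
    input_lower = model$input_bounds$lower, input_upper = model$input_bounds$upper,
    output_lower = model$output_bounds$lower, output_upper = model$output_bounds$upper,
    split_seed = model$split_seed, split_sizes = model$split_sizes,
    errors = as.list(model$errors), total_error = model$total_error)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "ventinvert_surrogate")) {
    stop("not a surrogate archive: ", path, call. = FALSE)
  }
  sizes <- as.integer(p$sizes)
  W <- lapply(p$W, as.matrix)
  net <- list(sizes = sizes, W = W, b = lapply(p$b, as.numeric))
  structure(list(net = net, topology = as.integer(p$topology),
                 input_bounds = vi_bounds(unlist(p$input_lower), unlist(p$input_upper)),
                 output_bounds = vi_bounds(unlist(p$output_lower), unlist(p$output_upper)),
                 split_seed = p$split_seed, split_sizes = unlist(p$split_sizes),
                 errors = unlist(p$errors), total_error = p$total_error),
            class = "surrogate_model")
}

#' @rdname write_surrogate
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(ensemble$k)
  for (j in seq_len(ensemble$k)) {
    files[j] <- file.path(dir, sprintf("model_%02d.json", j))
    write_surrogate(ensemble$models[[j]], files[j])
  }
  jsonlite::write_json(
    list(type = "ventinvert_ensemble", k = ensemble$k, seed = ensemble$seed,
         files = basename(files), all_errors = ensemble$all_errors),
    file.path(dir, "ensemble.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_surrogate
#' @export
read_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                             simplifyVector = TRUE)
  models <- lapply(file.path(dir, man$files), read_surrogate)
  structure(list(models = models, all_errors = man$all_errors,
                 k = as.integer(man$k), seed = man$seed),
            class = "surrogate_ensemble")
}
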
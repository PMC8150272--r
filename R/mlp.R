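# Feed-forward regression network: tanh hidden layers, linear output,
# full-batch Adam, early stopping on a validation split.  All training is on
# min-max normalized data; normalization is the caller's responsibility.
# Kept dependency-free on purpose: the topologies used here (<= a few dozen
# units, a few hundred records) train in seconds with plain matrix algebra.

mlp_init <- function(sizes) {
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    # Glorot-uniform keeps tanh pre-activations in their linear regime
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  list(sizes = sizes, W = W, b = b)
}

mlp_forward <- function(net, X) {
  n_layers <- length(net$W)
  A <- X
  for (l in seq_len(n_layers)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    A <- if (l < n_layers) tanh(Z) else Z
  }
  A
}

# mean squared error over all cells (used as the training loss)
mlp_loss <- function(net, X, Y) mean((mlp_forward(net, X) - Y)^2)

# sum of squared errors over all cells (used for model scoring)
mlp_sse <- function(net, X, Y) sum((mlp_forward(net, X) - Y)^2)

mlp_gradients <- function(net, X, Y) {
  n_layers <- length(net$W)
  n <- nrow(X)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  for (l in seq_len(n_layers)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < n_layers) tanh(Z) else Z
  }
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- 2 * (acts[[n_layers + 1L]] - Y) / (n * ncol(Y))
  for (l in rev(seq_len(n_layers))) {
    dW[[l]] <- crossprod(acts[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - acts[[l]]^2)
    }
  }
  list(dW = dW, db = db, fit = acts[[n_layers + 1L]])
}

#' @noRd
mlp_train <- function(X, Y, X_val = NULL, Y_val = NULL,
                      hidden = c(8, 16, 14),
                      epochs = 2000L, lr = 0.01,
                      patience = 200L, min_delta = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  sizes <- c(ncol(X), hidden, ncol(Y))
  net <- mlp_init(sizes)
  n_layers <- length(net$W)

  # Adam state
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  has_val <- !is.null(X_val) && nrow(as.matrix(X_val)) > 0L
  if (has_val) { X_val <- as.matrix(X_val); Y_val <- as.matrix(Y_val) }
  best_val <- Inf
  best_net <- net
  stall <- 0L
  history <- numeric(0)

  for (epoch in seq_len(epochs)) {
    g <- mlp_gradients(net, X, Y)
    for (l in seq_len(n_layers)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$dW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$dW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$db[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$db[[l]]^2
      mW_hat <- mW[[l]] / (1 - beta1^epoch)
      vW_hat <- vW[[l]] / (1 - beta2^epoch)
      mb_hat <- mb[[l]] / (1 - beta1^epoch)
      vb_hat <- vb[[l]] / (1 - beta2^epoch)
      net$W[[l]] <- net$W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
      net$b[[l]] <- net$b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
    }
    monitor <- if (has_val) mlp_loss(net, X_val, Y_val) else mlp_loss(net, X, Y)
    history <- c(history, monitor)
    if (monitor < best_val - min_delta) {
      best_val <- monitor
      best_net <- net
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  best_net$val_loss <- best_val
  best_net$epochs_run <- length(history)
  best_net$history <- history
  best_net
}
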
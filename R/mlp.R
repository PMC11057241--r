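# Feed-forward binary classifier with three hidden layers, written with
# base matrix algebra: ReLU activations, logistic output, binary
# cross-entropy loss, Adam updates on mini-batches, and early stopping on
# an internal holdout. Deterministic for a fixed seed.

mlp_init <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(rnorm(sizes[i] * sizes[i + 1], 0,
                          sqrt(2 / sizes[i])), sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- X
  for (i in seq_along(layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, `+`)
    acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

mlp_fit <- function(X, y, hidden = c(128, 64, 32), epochs = 60,
                    batch_size = 64, lr = 1e-3, val_frac = 0.1,
                    patience = 8, seed = 1) {
  stopifnot(length(hidden) == 3)
  X <- as.matrix(X)
  n <- nrow(X)
  with_seed(seed, {
    n_val <- max(1L, floor(n * val_frac))
    vi <- sample.int(n, n_val)
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    Xt <- X[-vi, , drop = FALSE]; yt <- y[-vi]
    layers <- mlp_init(ncol(X), hidden)
    mom <- lapply(layers, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                           mb = 0 * l$b, vb = 0 * l$b))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
    best <- list(loss = Inf, layers = layers, since = 0L)
    nt <- nrow(Xt)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nt)
      for (start in seq(1, nt, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nt)]
        acts <- mlp_forward(layers, Xt[idx, , drop = FALSE])
        m <- length(idx)
        delta <- (acts[[length(acts)]] - yt[idx]) / m  # dL/dz of logistic+BCE
        step <- step + 1
        for (i in rev(seq_along(layers))) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1) {
            delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
          }
          mo <- mom[[i]]
          mo$mW <- b1 * mo$mW + (1 - b1) * gW
          mo$vW <- b2 * mo$vW + (1 - b2) * gW^2
          mo$mb <- b1 * mo$mb + (1 - b1) * gb
          mo$vb <- b2 * mo$vb + (1 - b2) * gb^2
          mom[[i]] <- mo
          corr <- sqrt(1 - b2^step) / (1 - b1^step)
          layers[[i]]$W <- layers[[i]]$W - lr * corr * mo$mW / (sqrt(mo$vW) + eps)
          layers[[i]]$b <- layers[[i]]$b - lr * corr * mo$mb / (sqrt(mo$vb) + eps)
        }
      }
      pv <- mlp_forward(layers, Xv)[[length(layers) + 1]]
      pv <- clamp(pv, 1e-12, 1 - 1e-12)
      vloss <- -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, layers = layers, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
    list(layers = best$layers, hidden = hidden)
  })
}

mlp_predict <- function(fit, X) {
  as.vector(mlp_forward(fit$layers, as.matrix(X))[[length(fit$layers) + 1]])
}
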
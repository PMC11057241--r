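#' Classifier families compared by the pipeline
#'
#' @return Character vector in the fixed comparison (and tie-break) order.
#' @export
model_families <- function() {
  c("logreg_all", "logreg_backward", "svm", "random_forest", "neural_net")
}

#' Default hyperparameters per classifier family
#'
#' Conventional defaults: random forest with 500 trees and sqrt(p)
#' variables per split; RBF support-vector machine with cost 1 and kernel
#' width 1/p; backward stepwise logistic regression scored by AIC; neural
#' network with three hidden layers of 128/64/32 rectifier units, logistic
#' output and early stopping on a 10% internal holdout. All overridable
#' via `...`.
#'
#' @param family One of [model_families()].
#' @param ... Overrides.
#' @return Named list of hyperparameters.
#' @export
model_params <- function(family, ...) {
  defaults <- switch(family,
    logreg_all = list(),
    logreg_backward = list(criterion = "AIC"),
    svm = list(cost = 1),
    random_forest = list(num_trees = 500, mtry = NULL),
    neural_net = list(hidden = c(128, 64, 32), epochs = 60, batch_size = 64,
                      lr = 1e-3, val_frac = 0.1, patience = 8),
    stop("unknown model family: ", family, call. = FALSE)
  )
  utils::modifyList(defaults, list(...))
}

fit_logreg <- function(X, y, cols) {
  Xd <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  list(coef = fit$coefficients, cols = cols, aic = fit$aic)
}

predict_logreg <- function(fit, X) {
  beta <- fit$coef
  beta[is.na(beta)] <- 0
  eta <- cbind(1, X[, fit$cols, drop = FALSE]) %*% beta
  as.vector(1 / (1 + exp(-eta)))
}

# Greedy backward elimination: at each step refit without each remaining
# variable and drop the one whose removal lowers the AIC the most; stop
# when no removal improves it. Exact but O(p^2) model fits - intended for
# moderate feature counts.
fit_logreg_backward <- function(X, y) {
  cols <- seq_len(ncol(X))
  cur <- fit_logreg(X, y, cols)
  repeat {
    if (length(cols) == 0) break
    aics <- vapply(seq_along(cols), function(i) {
      fit_logreg(X, y, cols[-i])$aic
    }, numeric(1))
    if (min(aics) >= cur$aic) break
    drop_i <- which.min(aics)
    cols <- cols[-drop_i]
    cur <- fit_logreg(X, y, cols)
  }
  cur
}

#' Train one binary classifier
#'
#' @param family One of [model_families()].
#' @param X Numeric feature matrix (rows = nuclei), normalized to
#'   \[0, 1\].
#' @param y Binary 0/1 labels; both classes must be present.
#' @param params Hyperparameters from [model_params()].
#' @param seed Integer seed; training is deterministic per seed.
#' @return An object of class `ccphase_model` with a [predict_prob()]
#'   method returning class-1 probabilities.
#' @export
train_classifier <- function(family, X, y, params = model_params(family),
                             seed = 1) {
  family <- match.arg(family, model_families())
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  fit <- switch(family,
    logreg_all = fit_logreg(X, y, seq_len(ncol(X))),
    logreg_backward = fit_logreg_backward(X, y),
    svm = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                     kernel = "radial", cost = params$cost,
                     gamma = 1 / ncol(X), probability = TRUE, scale = FALSE),
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)),
      num.trees = params$num_trees,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(X)))),
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1
    ),
    neural_net = mlp_fit(X, y, hidden = params$hidden,
                         epochs = params$epochs,
                         batch_size = params$batch_size, lr = params$lr,
                         val_frac = params$val_frac,
                         patience = params$patience, seed = seed)
  )
  structure(list(family = family, fit = fit, params = params, seed = seed,
                 feature_names = colnames(X)),
            class = "ccphase_model")
}

#' Class-1 probability scores of a fitted classifier
#'
#' @param model A `ccphase_model`.
#' @param X Feature matrix with the training columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "ccphase_model"))
  X <- as.matrix(X)
  switch(model$family,
    logreg_all = predict_logreg(model$fit, X),
    logreg_backward = predict_logreg(model$fit, X),
    svm = {
      pr <- attr(predict(model$fit, X, probability = TRUE), "probabilities")
      as.vector(pr[, "1"])
    },
    random_forest = {
      as.vector(predict(model$fit, data = X, num.threads = 1)$predictions[, "1"])
    },
    neural_net = mlp_predict(model$fit, X)
  )
}

#' @export
print.ccphase_model <- function(x, ...) {
  cat(sprintf("<ccphase_model> family=%s, %d features\n", x$family,
              length(x$feature_names)))
  invisible(x)
}
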
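#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half
#' (equivalent to trapezoidal integration of the ROC curve). Computed via
#' midranks.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @return AUC in \[0, 1\]; `NA` if one class is absent.
#' @examples
#' auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' k-fold cross-validation of one classifier family
#'
#' Rows are shuffled once with `seed` and dealt into `k` equal folds
#' (non-stratified); for each fold the model is trained on the remaining
#' rows and scored on the held-out fold at probability cutoff 0.5.
#'
#' @param family One of [model_families()].
#' @param X,y Features and binary labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle and per-fold training.
#' @param params Hyperparameters from [model_params()].
#' @param task Optional task tag carried into the result.
#' @return An object of class `cv_result`: list with `task`, `family`,
#'   `fold_accuracies` (length `k`) and `mean_accuracy`.
#' @export
cross_validate <- function(family, X, y, k = 10, seed = 1,
                           params = model_params(family), task = NA) {
  n <- nrow(X)
  if (n < k) stop("fewer rows than folds", call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), length.out = n)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_classifier(family, X[tr, , drop = FALSE], y[tr],
                              params = params,
                              seed = derive_seed(seed, paste0("fold", f)))
    p <- predict_prob(model, X[!tr, , drop = FALSE])
    mean((p >= 0.5) == (y[!tr] == 1))
  }, numeric(1))
  structure(list(task = task, family = family, fold_accuracies = acc,
                 mean_accuracy = mean(acc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s%s: mean accuracy %.3f over %d folds\n",
              x$family, if (is.na(x$task)) "" else paste0(" [", x$task, "]"),
              x$mean_accuracy, length(x$fold_accuracies)))
  invisible(x)
}

#' Select the best family from cross-validation results
#'
#' Argmax of mean CV accuracy. Ties are broken without touching the
#' validation data: first by the higher minimum fold accuracy, then by the
#' fixed family order of [model_families()].
#'
#' @param results List of `cv_result` objects (one task).
#' @return The selected family name (character).
#' @export
select_best <- function(results) {
  stopifnot(length(results) >= 1)
  means <- vapply(results, `[[`, 0, "mean_accuracy")
  mins <- vapply(results, function(r) min(r$fold_accuracies), 0)
  fam <- vapply(results, `[[`, "", "family")
  ord <- order(-means, -mins, match(fam, model_families()))
  fam[ord[1]]
}

#' Evaluate a fitted classifier on validation data
#'
#' Confusion counts at probability cutoff 0.5, accuracy, sensitivity
#' (TP / (TP + FN), 0 for 0/0), specificity (TN / (TN + FP), 0 for 0/0)
#' and AUC.
#'
#' @param model A `ccphase_model`.
#' @param X_val,y_val Validation features and binary labels.
#' @param cutoff Probability cutoff (default 0.5).
#' @return An object of class `evaluation_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, and counts `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
evaluate_model <- function(model, X_val, y_val, cutoff = 0.5) {
  if (nrow(as.matrix(X_val)) == 0) {
    stop("empty validation set", call. = FALSE)
  }
  p <- predict_prob(model, X_val)
  pred <- as.integer(p >= cutoff)
  y <- as.integer(y_val)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  div0 <- function(a, b) if (b == 0) 0 else a / b
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = div0(tp, tp + fn),
    specificity = div0(tn, tn + fp),
    auc = auc_score(p, y),
    TP = tp, FP = fp, TN = tn, FN = fn
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> accuracy %.3f, sensitivity %.3f, ",
                     "specificity %.3f, AUC %.3f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Random-forest feature importance ranking
#'
#' Mean-decrease-in-impurity importances of a fitted random forest,
#' normalized to sum 1 and sorted in descending order.
#'
#' @param model A `ccphase_model` with family `random_forest`.
#' @param top_k Number of top features reported in the `top` element.
#' @return List with `ranking` (data.frame `feature`, `importance`, all
#'   240 rows) and `top` (first `top_k` rows).
#' @export
feature_importance <- function(model, top_k = 10) {
  stopifnot(inherits(model, "ccphase_model"))
  if (model$family != "random_forest") {
    stop("feature importance is reported for the random forest only",
         call. = FALSE)
  }
  imp <- ranger::importance(model$fit)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp)
  ranking <- data.frame(feature = names(imp)[ord],
                        importance = unname(imp[ord]))
  list(ranking = ranking, top = head(ranking, top_k))
}
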
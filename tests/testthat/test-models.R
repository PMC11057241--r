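make_xy <- function(n, p, seed, signal = 0) {
  ccphase:::with_seed(seed, {
    X <- matrix(runif(n * p), n, p)
    colnames(X) <- sprintf("f%02d", seq_len(p))
    eta <- if (signal > 0) {
      signal * (X[, 1] + X[, 2] - X[, 3] - 0.5)
    } else {
      rep(0, n)
    }
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    list(X = X, y = y)
  })
}

fast_nn <- model_params("neural_net", hidden = c(32, 16, 8), epochs = 150,
                        batch_size = 32, lr = 0.01, patience = 30)

test_that("every family separates a linearly separable toy set", {
  d <- ccphase:::with_seed(31, {
    X <- matrix(runif(400), 200, 2)
    colnames(X) <- c("u", "v")
    y <- as.integer(X[, 1] - X[, 2] > 0)
    keep <- abs(X[, 1] - X[, 2]) > 0.05  # margin
    list(X = X[keep, ], y = y[keep])
  })
  for (fam in model_families()) {
    params <- if (fam == "neural_net") fast_nn else model_params(fam)
    model <- train_classifier(fam, d$X, d$y, params = params, seed = 32)
    acc <- mean((predict_prob(model, d$X) >= 0.5) == (d$y == 1))
    expect_gte(acc, 0.99)
  }
  expect_error(train_classifier("logreg_all", d$X, rep(1, nrow(d$X))),
               "single class")
})

test_that("label-independent features give chance-level cross-validation", {
  d <- make_xy(2000, 15, seed = 33, signal = 0)
  base <- max(mean(d$y), 1 - mean(d$y))
  sd3 <- 3 * sqrt(base * (1 - base) / 2000)
  for (fam in c("logreg_all", "random_forest")) {
    params <- if (fam == "random_forest") {
      model_params(fam, num_trees = 100)
    } else {
      model_params(fam)
    }
    cv <- cross_validate(fam, d$X, d$y, k = 10, seed = 34, params = params)
    expect_lt(abs(cv$mean_accuracy - base), sd3 + 0.01)
  }
})

test_that("backward elimination keeps the variables that carry signal", {
  d <- make_xy(2000, 10, seed = 35, signal = 6)
  model <- train_classifier("logreg_backward", d$X, d$y, seed = 36)
  expect_true(all(1:3 %in% model$fit$cols))
  expect_lt(length(model$fit$cols), 10)  # some pure-noise columns dropped
  # the reduced model scores like the full one on fresh data
  fresh <- make_xy(1000, 10, seed = 37, signal = 6)
  acc <- mean((predict_prob(model, fresh$X) >= 0.5) == (fresh$y == 1))
  expect_gt(acc, 0.7)
})

test_that("cross-validation is deterministic per seed and near 0.5 for a constant model", {
  d <- make_xy(300, 3, seed = 38, signal = 0)
  Xconst <- matrix(0.5, 300, 2, dimnames = list(NULL, c("c1", "c2")))
  cv <- cross_validate("logreg_all", Xconst, d$y, k = 10, seed = 39)
  expect_length(cv$fold_accuracies, 10)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_lt(abs(cv$mean_accuracy - 0.5), 0.1)
  cv2 <- cross_validate("logreg_all", Xconst, d$y, k = 10, seed = 39)
  expect_identical(cv$fold_accuracies, cv2$fold_accuracies)
  expect_error(cross_validate("logreg_all", Xconst[1:5, ], d$y[1:5], k = 10),
               "fewer rows")
})

test_that("model selection follows accuracy with principled tie-breaking", {
  mk <- function(fam, accs) {
    structure(list(task = "G1", family = fam, fold_accuracies = accs,
                   mean_accuracy = mean(accs)), class = "cv_result")
  }
  res <- list(mk("logreg_all", rep(0.751, 10)),
              mk("logreg_backward", rep(0.761, 10)),
              mk("svm", rep(0.753, 10)),
              mk("neural_net", rep(0.743, 10)),
              mk("random_forest", rep(0.777, 10)))
  expect_equal(select_best(res), "random_forest")
  # tie on the mean: higher minimum fold accuracy wins
  tie <- list(mk("svm", c(0.7, 0.9)), mk("random_forest", c(0.79, 0.81)))
  expect_equal(select_best(tie), "random_forest")
  # full tie: fixed family order
  full <- list(mk("svm", c(0.8, 0.8)), mk("random_forest", c(0.8, 0.8)))
  expect_equal(select_best(full), "svm")
  expect_equal(select_best(list(mk("svm", rep(0.6, 10)))), "svm")
})

test_that("evaluation metrics match hand-computed confusion and AUC", {
  model <- structure(list(family = "logreg_all",
                          fit = list(coef = c(0, 1), cols = 1),
                          feature_names = "s"),
                     class = "ccphase_model")
  # identity-ish scoring: probability increases with the single feature
  X <- cbind(s = c(2.2, 1.4, 0.85, 0.4))
  p <- predict_prob(model, X)
  expect_true(all(diff(p) < 0))
  ev <- evaluate_model(model, X, c(1, 0, 1, 0))
  expect_equal(ev$auc, 0.75)  # 3 of 4 concordant pairs
  expect_equal(ev$accuracy, 0.5)

  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  # all positives predicted negative: sensitivity 0, specificity 1
  ev2 <- evaluate_model(model, cbind(s = c(-5, -4, -3)), c(1, 1, 0))
  expect_equal(ev2$sensitivity, 0)
  expect_equal(ev2$specificity, 1)
  expect_error(evaluate_model(model, cbind(s = numeric(0)), integer(0)),
               "empty")
})

test_that("rank-based AUC equals brute-force pairwise concordance", {
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  ccphase:::with_seed(40, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      expect_equal(auc_score(s, y), brute_auc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("random-forest importance surfaces planted signal features", {
  d <- ccphase:::with_seed(41, {
    X <- matrix(runif(1500 * 30), 1500, 30)
    colnames(X) <- c("Intensity Nucleus Sum", "Nucleus Area",
                     "Nucleus Radial Mean", sprintf("noise%02d", 1:27))
    y <- as.integer(X[, 1] > 0.5)
    list(X = X, y = y)
  })
  model <- train_classifier("random_forest", d$X, d$y,
                            params = model_params("random_forest",
                                                  num_trees = 200),
                            seed = 42)
  imp <- feature_importance(model)
  expect_equal(sum(imp$ranking$importance), 1, tolerance = 1e-9)
  expect_equal(imp$ranking$feature[1], "Intensity Nucleus Sum")
  expect_gt(imp$ranking$importance[1], 0.5)
  expect_error(feature_importance(train_classifier("logreg_all", d$X, d$y)),
               "random forest")

  # three planted signals all stay in the top 10
  d3 <- ccphase:::with_seed(43, {
    X <- matrix(runif(1500 * 30), 1500, 30)
    colnames(X) <- c(sprintf("signal%d", 1:3), sprintf("noise%02d", 1:27))
    y <- rbinom(1500, 1, stats::plogis(5 * (X[, 1] + X[, 2] + X[, 3] - 1.5)))
    list(X = X, y = y)
  })
  m3 <- train_classifier("random_forest", d3$X, d3$y,
                         params = model_params("random_forest",
                                               num_trees = 200), seed = 44)
  top10 <- feature_importance(m3)$top$feature
  expect_true(all(sprintf("signal%d", 1:3) %in% top10))
})

test_that("the neural network trains deterministically per seed", {
  d <- make_xy(400, 8, seed = 45, signal = 4)
  m1 <- train_classifier("neural_net", d$X, d$y, params = fast_nn, seed = 46)
  m2 <- train_classifier("neural_net", d$X, d$y, params = fast_nn, seed = 46)
  expect_identical(predict_prob(m1, d$X), predict_prob(m2, d$X))
  acc <- mean((predict_prob(m1, d$X) >= 0.5) == (d$y == 1))
  expect_gt(acc, 0.7)
})

test_that("the random forest dominates linear baselines and tracks the best model", {
  # Backward-stepwise regression is exercised on small fixtures above; its
  # greedy AIC elimination is quadratic in the 240 features and is left out
  # of this seed loop. The three-layer network is the forest's only close
  # competitor on this data, so the asserted property is: the forest beats
  # both linear-kernel-free baselines on every seed and task, and never
  # trails the best family by more than three accuracy points (3-fold CV).
  gated <- demo_gated()
  sp <- sample_and_normalize(gated$features, gated$nuclei,
                             n_train = floor(nrow(gated$features) * 0.85),
                             n_val = floor(nrow(gated$features) * 0.1),
                             seed = 47)
  families <- c("logreg_all", "svm", "random_forest", "neural_net")
  for (s in 1:10) {
    for (task in c("G1", "SG2M")) {
      y <- sp$train_info[[paste0("label_", task)]]
      means <- vapply(families, function(fam) {
        cross_validate(fam, sp$train_x, y, k = 3, seed = s,
                       params = model_params(fam))$mean_accuracy
      }, numeric(1))
      names(means) <- families
      expect_gt(means[["random_forest"]], means[["logreg_all"]])
      expect_gt(means[["random_forest"]], means[["svm"]])
      expect_gte(means[["random_forest"]], max(means) - 0.03)
    }
  }
})
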
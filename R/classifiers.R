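#' Specification of one of the seven benchmark classifiers
#'
#' Fixes each classifier's hyperparameters to the benchmark settings:
#' LDA has none; both SVMs use C = 1 (sigma = 1 for the RBF kernel); the
#' random forest grows 1000 trees with per-tree balanced class subsampling;
#' AdaBoost uses 1000 trees; stochastic gradient boosting (SGB) uses 1000
#' trees, learning rate 0.1 and subsample fraction 0.5; RUSBoost uses 1000
#' trees with learning rate 0.1 and per-iteration random undersampling of the
#' majority class. `n_trees` is exposed so reduced ensembles can be run on
#' small problems; the other settings are part of the benchmark definition.
#'
#' @param name One of `"LDA"`, `"SVMlin"`, `"SVMrbf"`, `"RF"`, `"AdaBoost"`,
#'   `"SGB"`, `"RUSBoost"`.
#' @param n_trees Ensemble size override (default: the benchmark's 1000).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(name = c("LDA", "SVMlin", "SVMrbf", "RF",
                                     "AdaBoost", "SGB", "RUSBoost"),
                            n_trees = NULL) {
  name <- match.arg(name)
  params <- switch(name,
    LDA = list(),
    SVMlin = list(C = 1),
    SVMrbf = list(C = 1, sigma = 1),
    RF = list(n_trees = n_trees %||% 1000L),
    AdaBoost = list(n_trees = n_trees %||% 1000L, learn_rate = 1,
                    max_depth = 1L),
    SGB = list(n_trees = n_trees %||% 1000L, learn_rate = 0.1,
               subsample = 0.5, max_depth = 3L),
    RUSBoost = list(n_trees = n_trees %||% 1000L, learn_rate = 0.1,
                    max_depth = 1L))
  structure(list(name = name, params = params), class = "classifier_spec")
}

#' The full benchmark set of seven classifier specs
#'
#' @inheritParams classifier_spec
#' @return Named list of seven [classifier_spec()] objects.
#' @export
default_classifier_specs <- function(n_trees = NULL) {
  nm <- c("LDA", "SVMlin", "SVMrbf", "RF", "AdaBoost", "SGB", "RUSBoost")
  setNames(lapply(nm, classifier_spec, n_trees = n_trees), nm)
}

majority_class <- function(y) names(which.max(table(y)))

fit_stump <- function(X, y, w, max_depth) {
  d <- data.frame(.y = factor(y, levels = CLASS_LEVELS), X, check.names = FALSE)
  rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
               control = rpart::rpart.control(maxdepth = max_depth,
                                              minsplit = 2, minbucket = 1,
                                              cp = 0, xval = 0,
                                              maxcompete = 0,
                                              maxsurrogate = 0))
}

predict_stump <- function(fit, X) {
  as.character(predict(fit, newdata = as.data.frame(X), type = "class"))
}

# Discrete (two-class SAMME) AdaBoost over depth-limited rpart trees.
fit_adaboost <- function(X, y, n_trees, learn_rate = 1, max_depth = 1L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  models <- list(); alphas <- numeric(0)
  for (t in seq_len(n_trees)) {
    fit <- fit_stump(X, y, w * n, max_depth)
    pred <- predict_stump(fit, X)
    mis <- pred != y
    err <- sum(w[mis])
    if (err <= 0) {                     # perfect learner: dominate the vote
      models[[length(models) + 1L]] <- fit
      alphas <- c(alphas, learn_rate * log(1e10))
      break
    }
    if (err >= 0.5) break               # no better than chance: stop boosting
    alpha <- learn_rate * log((1 - err) / err)
    models[[length(models) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  list(models = models, alphas = alphas, fallback = majority_class(y))
}

# RUSBoost: AdaBoost-style reweighting where each iteration's learner is fit
# on a random undersample of the majority class (down to the minority count,
# drawn with the current boosting weights), per Seiffert et al.'s algorithm.
fit_rusboost <- function(X, y, n_trees, learn_rate = 0.1, max_depth = 1L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  cls <- table(y)
  minority <- names(which.min(cls))
  models <- list(); alphas <- numeric(0)
  for (t in seq_len(n_trees)) {
    idx_min <- which(y == minority)
    idx_maj <- which(y != minority)
    take <- sample(idx_maj, size = min(length(idx_min), length(idx_maj)),
                   prob = w[idx_maj])
    idx <- c(idx_min, take)
    fit <- fit_stump(X[idx, , drop = FALSE], y[idx], w[idx] * length(idx),
                     max_depth)
    pred <- predict_stump(fit, X)
    mis <- pred != y
    err <- sum(w[mis])
    if (err >= 0.5) next                # resample and retry next iteration
    err <- max(err, 1e-10)
    beta <- err / (1 - err)
    models[[length(models) + 1L]] <- fit
    alphas <- c(alphas, learn_rate * log(1 / beta))
    w <- w * beta^(learn_rate * (1 - mis))
    w <- w / sum(w)
  }
  list(models = models, alphas = alphas, fallback = majority_class(y))
}

predict_boosted <- function(model, X) {
  if (!length(model$models)) {
    return(rep(model$fallback, nrow(X)))
  }
  score <- rep(0, nrow(X))
  for (t in seq_along(model$models)) {
    pred <- predict_stump(model$models[[t]], X)
    score <- score + model$alphas[t] * ifelse(pred == CLASS_LEVELS[1], 1, -1)
  }
  ifelse(score >= 0, CLASS_LEVELS[1], CLASS_LEVELS[2])
}

# Train one classifier and predict test labels. X already scaled to [0, 1].
# Degenerate fits (e.g. LDA on a zero-within-class-variance feature) fall
# back to the training majority class rather than aborting a whole fold.
fit_predict <- function(spec, X_train, y_train, X_test, seed) {
  set.seed(seed)
  X_train <- as.data.frame(X_train, check.names = FALSE)
  X_test <- as.data.frame(X_test, check.names = FALSE)
  y <- as.character(y_train)
  p <- spec$params
  fallback <- function(e) rep(majority_class(y), nrow(X_test))
  suppressWarnings(tryCatch(
    switch(spec$name,
      LDA = {
        fit <- MASS::lda(x = X_train, grouping = factor(y, CLASS_LEVELS))
        as.character(predict(fit, newdata = X_test)$class)
      },
      SVMlin = {
        fit <- kernlab::ksvm(as.matrix(X_train), factor(y, CLASS_LEVELS),
                             type = "C-svc", kernel = "vanilladot",
                             kpar = list(), C = p$C, scaled = FALSE)
        as.character(kernlab::predict(fit, as.matrix(X_test)))
      },
      SVMrbf = {
        fit <- kernlab::ksvm(as.matrix(X_train), factor(y, CLASS_LEVELS),
                             type = "C-svc", kernel = "rbfdot",
                             kpar = list(sigma = p$sigma), C = p$C,
                             scaled = FALSE)
        as.character(kernlab::predict(fit, as.matrix(X_test)))
      },
      RF = {
        nmin <- min(table(y))
        fit <- randomForest::randomForest(
          x = X_train, y = factor(y, CLASS_LEVELS), ntree = p$n_trees,
          strata = factor(y, CLASS_LEVELS),
          sampsize = rep(nmin, 2))        # balanced subsample per tree
        as.character(predict(fit, X_test))
      },
      AdaBoost = {
        fit <- fit_adaboost(X_train, y, p$n_trees, p$learn_rate, p$max_depth)
        predict_boosted(fit, X_test)
      },
      SGB = {
        dtrain <- xgboost::xgb.DMatrix(
          as.matrix(X_train),
          label = as.integer(y == CLASS_LEVELS[1]))
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = p$learn_rate,
                        subsample = p$subsample, max_depth = p$max_depth,
                        lambda = 0, nthread = 1),
          data = dtrain, nrounds = p$n_trees, verbose = 0)
        prob <- predict(fit, as.matrix(X_test))
        ifelse(prob >= 0.5, CLASS_LEVELS[1], CLASS_LEVELS[2])
      },
      RUSBoost = {
        fit <- fit_rusboost(X_train, y, p$n_trees, p$learn_rate, p$max_depth)
        predict_boosted(fit, X_test)
      }),
    error = fallback))
}
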
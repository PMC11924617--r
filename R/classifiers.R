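#' Candidate classifier roster
#'
#' Uniform fit/predict wrappers around seven candidate classifiers:
#' logistic regression (`lr`, ridge-penalized via glmnet), support vector
#' machine (`svm`, RBF kernel via e1071), k-nearest neighbours (`knn`),
#' decision tree (`dt`, rpart), random forest (`rf`, ranger), gradient
#' boosting (`gbdt`, xgboost) and AdaBoost (`adaboost`, SAMME with
#' depth-1 rpart stumps, implemented here). Each exposes exactly two tuned
#' hyperparameters:
#'
#' | name | hyperparameters |
#' |------|-----------------|
#' | lr | `cost` (inverse regularization), `maxit` |
#' | svm | `cost`, `gamma` |
#' | knn | `k`, `leaf_size` |
#' | dt | `maxdepth`, `minbucket` |
#' | rf | `maxdepth`, `min_node` |
#' | gbdt | `nrounds`, `eta` |
#' | adaboost | `n_estimators`, `learning_rate` |
#'
#' `leaf_size` parametrizes the neighbour-search tree and does not change
#' predictions (as in the reference implementations); it is kept for
#' interface parity.
#'
#' Feature matrices are z-scored internally with a scaler fitted on the
#' training rows, so scale-sensitive candidates (svm, knn, lr) see
#' standardized inputs.
#'
#' @param name roster name (above).
#' @param x numeric feature matrix (training rows).
#' @param y two-level factor of labels; the second level is the positive
#'   class.
#' @param params named list of the classifier's two hyperparameters;
#'   `NULL` = the documented defaults.
#' @param seed integer seed for the stochastic candidates.
#' @return `fit_classifier()`: an object of class `gait_clf` with a
#'   [predict][predict.gait_clf] method returning label factors.
#' @export
fit_classifier <- function(name, x, y, params = NULL, seed = 1L) {
  name <- match.arg(name, c("lr", "svm", "knn", "dt", "rf", "gbdt", "adaboost"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need exactly 2 classes, got ", nlevels(y))
  if (is.null(params)) params <- default_params(name, ncol(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, ctr, scl)
  set.seed(seed)
  fit <- switch(name,
    lr = glmnet::glmnet(pad1(xs), y, family = "binomial", alpha = 0,
                        lambda = 1 / (params$cost * nrow(xs)),
                        maxit = params$maxit),
    svm = e1071::svm(xs, y, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, scale = FALSE),
    knn = list(x = xs, y = y, k = params$k, leaf_size = params$leaf_size),
    dt = rpart::rpart(label ~ ., data = data.frame(label = y, xs),
                      method = "class",
                      control = rpart::rpart.control(
                        maxdepth = params$maxdepth,
                        minbucket = params$minbucket,
                        minsplit = 2, cp = 0, xval = 0)),
    rf = ranger::ranger(x = xs, y = y, num.trees = 200,
                        max.depth = params$maxdepth,
                        min.node.size = params$min_node,
                        seed = seed, num.threads = 1),
    gbdt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = 3, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(xs, label = as.numeric(y) - 1,
                                  nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    adaboost = fit_adaboost(xs, y, params$n_estimators,
                            params$learning_rate))
  structure(list(name = name, fit = fit, params = params,
                 levels = levels(y), center = ctr, scale = scl),
            class = "gait_clf")
}

#' Default hyperparameters per candidate
#' @param name roster name.
#' @param p feature dimension (sets the default svm `gamma = 1/p`).
#' @return named list of the two hyperparameters.
#' @export
default_params <- function(name, p = 5) {
  switch(name,
    lr = list(cost = 1, maxit = 100),
    svm = list(cost = 1, gamma = 1 / max(p, 1)),
    knn = list(k = 5, leaf_size = 30),
    dt = list(maxdepth = 5, minbucket = 3),
    rf = list(maxdepth = 6, min_node = 2),
    gbdt = list(nrounds = 100, eta = 0.1),
    adaboost = list(n_estimators = 50, learning_rate = 1))
}

#' Hyperparameter search grids
#'
#' Two-parameter grids searched by [tune_branch()]; the `fast` variant
#' shrinks each grid for scaled-down experiments.
#'
#' @param fast logical; use the reduced grids.
#' @return named list of data.frames, one row per candidate setting.
#' @export
default_grids <- function(fast = FALSE) {
  if (fast) {
    list(lr = expand.grid(cost = c(0.1, 1), maxit = 100),
         svm = expand.grid(cost = c(0.5, 2), gamma = c(0.1, 0.5)),
         knn = expand.grid(k = c(3, 7), leaf_size = 30),
         dt = expand.grid(maxdepth = c(2, 5), minbucket = 3),
         rf = expand.grid(maxdepth = c(4, 8), min_node = 2),
         gbdt = expand.grid(nrounds = 60, eta = c(0.1, 0.3)),
         adaboost = expand.grid(n_estimators = 30, learning_rate = c(0.5, 1)))
  } else {
    list(lr = expand.grid(cost = c(0.01, 0.1, 1, 10), maxit = c(25, 100)),
         svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.05, 0.2, 1)),
         knn = expand.grid(k = c(3, 5, 9), leaf_size = c(15, 30)),
         dt = expand.grid(maxdepth = c(2, 4, 8), minbucket = c(1, 5)),
         rf = expand.grid(maxdepth = c(3, 6, 10), min_node = c(1, 5)),
         gbdt = expand.grid(nrounds = c(50, 150), eta = c(0.05, 0.2)),
         adaboost = expand.grid(n_estimators = c(25, 75),
                                learning_rate = c(0.5, 1)))
  }
}

#' @rdname fit_classifier
#' @param object a fitted `gait_clf`.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @export
predict.gait_clf <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  lev <- object$levels
  out <- switch(object$name,
    lr = lev[1 + (as.vector(
      stats::predict(object$fit, pad1(xs), type = "response")) > 0.5)],
    svm = as.character(stats::predict(object$fit, xs)),
    knn = as.character(class::knn(object$fit$x, xs, object$fit$y,
                                  k = min(object$fit$k, nrow(object$fit$x)))),
    dt = as.character(stats::predict(object$fit,
                                     as.data.frame(xs), type = "class")),
    rf = as.character(stats::predict(object$fit, data = xs,
                                     num.threads = 1)$predictions),
    gbdt = lev[1 + (stats::predict(object$fit,
                                   xgboost::xgb.DMatrix(xs, nthread = 1)) >
                      0.5)],
    adaboost = predict_adaboost(object$fit, xs, lev))
  factor(out, levels = lev)
}

# glmnet needs >= 2 columns; pad a zero column for 1-feature models
pad1 <- function(x) if (ncol(x) == 1L) cbind(x, .pad = 0) else x

# SAMME AdaBoost with depth-1 rpart stumps (two-class)
fit_adaboost <- function(x, y, n_estimators, learning_rate) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y == levels(y)[2], 1, -1)
  df <- data.frame(label = y, x)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(label ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2, cp = 0,
                                                       xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == levels(y)[2],
                   1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5 - 1e-10) break
    err <- max(err, 1e-10)
    a <- learning_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, a)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) {  # no stump beats chance: fall back to majority class
    maj <- levels(y)[which.max(tabulate(y))]
    return(list(stumps = list(), alphas = numeric(0), majority = maj))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL)
}

predict_adaboost <- function(fit, xs, lev) {
  if (!length(fit$stumps)) return(rep(fit$majority, nrow(xs)))
  df <- as.data.frame(xs)
  score <- rep(0, nrow(xs))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(stats::predict(fit$stumps[[m]], df, type = "class") ==
                     lev[2], 1, -1)
    score <- score + fit$alphas[m] * pred
  }
  ifelse(score >= 0, lev[2], lev[1])
}
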
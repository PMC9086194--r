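#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties.
#'
#' @param score Numeric scores for the positive class.
#' @param y Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(score, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classifier_names <- function() {
  c("svm_linear", "svm_poly", "svm_radial", "knn", "rf", "xgb",
    "ridge", "lasso")
}

#' Fit a classifier on selected features and evaluate on held-out data
#'
#' Fits one of eight classifiers (linear/polynomial/radial SVM, k-nearest
#' neighbours, random forest, gradient boosting, ridge and lasso logistic
#' regression) on the training data restricted to the selected features,
#' and reports accuracy (0.5 probability cutoff / native class
#' prediction) and rank-based AUC on the test data.  SVM cost and KNN
#' neighbourhood size are tuned by a small seeded cross-validated grid on
#' the training data; ridge/lasso tune lambda by cross-validated
#' deviance; the tree ensembles use fixed standard settings.
#'
#' With an empty feature set the majority training class is predicted
#' (with a warning) and AUC is 0.5.
#'
#' @param X_train,y_train Training data (labels 0/1).
#' @param X_test,y_test Held-out data.
#' @param features Integer indices of the features to use.
#' @param method One of `classifier_names()`.
#' @param seed Seed for tuning folds and stochastic learners.
#' @return List with `method`, `accuracy`, `auc`, `n_features`.
#' @export
classify <- function(X_train, y_train, X_test, y_test, features,
                     method = classifier_names(), seed = 1L) {
  method <- match.arg(method)
  d <- check_xy(X_train, y_train); X_train <- d$X; y_train <- d$y
  X_test <- as.matrix(X_test); y_test <- as.integer(y_test)
  if (!length(features)) {
    warning("empty feature set: falling back to majority-class prediction")
    maj <- as.integer(mean(y_train) >= 0.5)
    return(list(method = method, accuracy = mean(y_test == maj), auc = 0.5,
                n_features = 0L))
  }
  Xtr <- X_train[, features, drop = FALSE]
  Xte <- X_test[, features, drop = FALSE]
  ## standardize with training statistics
  mu <- colMeans(Xtr); sd <- apply(Xtr, 2L, stats::sd); sd[sd == 0] <- 1
  Xtr <- scale(Xtr, mu, sd); Xte <- scale(Xte, mu, sd)
  yf <- factor(y_train, levels = c(0L, 1L))
  set.seed(as.integer(seed))

  score <- switch(method,
    svm_linear = svm_score(Xtr, yf, Xte, "linear", seed),
    svm_poly   = svm_score(Xtr, yf, Xte, "polynomial", seed),
    svm_radial = svm_score(Xtr, yf, Xte, "radial", seed),
    knn = {
      k <- tune_knn(Xtr, yf, seed)
      pr <- class::knn(Xtr, Xte, yf, k = k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    rf = {
      df <- as.data.frame(Xtr); df$.y <- yf
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            num.trees = 500L, probability = TRUE,
                            seed = seed, num.threads = 1L)
      stats::predict(fit, as.data.frame(Xte))$predictions[, "1"]
    },
    xgb = {
      fit <- xgboost::xgboost(Xtr, yf, nrounds = 50L, max_depth = 3L,
                              learning_rate = 0.3, nthreads = 1L,
                              verbosity = 0)
      stats::predict(fit, Xte, type = "response")  # P(class "1")
    },
    ridge = glmnet_score(Xtr, y_train, Xte, alpha = 0, seed),
    lasso = glmnet_score(Xtr, y_train, Xte, alpha = 1, seed))

  list(method = method,
       accuracy = mean((score >= 0.5) == (y_test == 1L)),
       auc = auc_score(score, y_test),
       n_features = length(features))
}

## probability-scale score for class 1 from an SVM with Platt scaling
svm_score <- function(Xtr, yf, Xte, kernel, seed) {
  cost <- tune_svm_cost(Xtr, yf, kernel, seed)
  fit <- e1071::svm(Xtr, yf, kernel = kernel, cost = cost, scale = FALSE,
                    probability = TRUE)
  pr <- stats::predict(fit, Xte, probability = TRUE)
  attr(pr, "probabilities")[, "1"]
}

tune_svm_cost <- function(Xtr, yf, kernel, seed, grid = c(0.1, 1, 10)) {
  if (nrow(Xtr) < 10L) return(1)
  fold <- stratified_folds(as.integer(yf) - 1L, 3L, seed)
  acc <- vapply(grid, function(cost) {
    mean(vapply(1:3, function(f) {
      tr <- fold != f
      if (length(unique(yf[tr])) < 2L || length(unique(yf[!tr])) < 1L)
        return(NA_real_)
      fit <- e1071::svm(Xtr[tr, , drop = FALSE], yf[tr], kernel = kernel,
                        cost = cost, scale = FALSE)
      mean(stats::predict(fit, Xtr[!tr, , drop = FALSE]) == yf[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]
}

tune_knn <- function(Xtr, yf, seed, grid = c(3L, 5L, 7L)) {
  grid <- grid[grid < nrow(Xtr)]
  if (!length(grid)) return(1L)
  fold <- stratified_folds(as.integer(yf) - 1L, 3L, seed)
  acc <- vapply(grid, function(k) {
    mean(vapply(1:3, function(f) {
      tr <- fold != f
      if (sum(tr) <= k) return(NA_real_)
      mean(class::knn(Xtr[tr, , drop = FALSE], Xtr[!tr, , drop = FALSE],
                      yf[tr], k = k) == yf[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]
}

glmnet_score <- function(Xtr, ytr, Xte, alpha, seed) {
  if (ncol(Xtr) < 2L) {   # glmnet needs >= 2 columns; pad with a constant
    Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0)
  }
  foldid <- stratified_folds(ytr, min(5L, min(table(ytr))), seed)
  fit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = alpha,
                           foldid = foldid)
  drop(stats::predict(fit, Xte, s = "lambda.min", type = "response"))
}

#' Cross-validated feature selection with held-out evaluation
#'
#' Splits the samples into stratified folds; in each fold the selector
#' runs on the training portion and each requested classifier is fitted
#' on the training portion (restricted to that fold's selection) and
#' evaluated on the held-out fold.  Selection frequency across folds is
#' summarized by the weighted relative frequency, and the headline set
#' contains the features selected in at least `min_folds` folds.
#'
#' @param X,y Feature matrix and binary labels.
#' @param selector Function `(X, y, seed) -> integer feature indices`.
#' @param classifiers Character vector among `classifier_names()`.
#' @param folds Number of folds (default 5).
#' @param min_folds Minimum number of folds a feature must be selected
#'   in to enter the headline set (default 2).
#' @param seed Master seed.
#' @return List: `fold_selections`, `wrf` (named by feature index),
#'   `headline` (indices selected in `>= min_folds` folds),
#'   `prediction` (data frame fold x classifier with accuracy and AUC).
#' @export
cross_validated_selection <- function(X, y, selector,
                                      classifiers = "svm_linear",
                                      folds = 5L, min_folds = 2L, seed = 1L) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  stopifnot(nrow(X) >= folds)
  fold <- stratified_folds(y, folds, seed)
  seeds <- derive_seeds(seed + 1L, folds)
  sels <- vector("list", folds)
  pred <- list()
  for (f in seq_len(folds)) {
    tr <- fold != f
    sels[[f]] <- sort(as.integer(selector(X[tr, , drop = FALSE], y[tr],
                                          seeds[f])))
    for (cl in classifiers) {
      res <- classify(X[tr, , drop = FALSE], y[tr],
                      X[!tr, , drop = FALSE], y[!tr],
                      sels[[f]], method = cl, seed = seeds[f])
      pred[[length(pred) + 1L]] <- data.frame(
        fold = f, classifier = cl, accuracy = res$accuracy, auc = res$auc,
        n_features = res$n_features, stringsAsFactors = FALSE)
    }
  }
  wrf <- weighted_relative_frequency(sels, features = seq_len(ncol(X)))
  counts <- tabulate(unlist(lapply(sels, unique)), ncol(X))
  list(fold_selections = sels, wrf = wrf,
       headline = which(counts >= min_folds),
       prediction = do.call(rbind, pred))
}
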
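#' SVM-RFE feature ranking
#'
#' Recursive feature elimination driven by linear support-vector-machine
#' weights.  At each round a linear SVM is fitted on each of `cv_folds`
#' cross-validation training splits; the squared weights are normalized
#' within fold and averaged, and the lowest-scoring `rfe_step_frac` of
#' the remaining features are eliminated.  Once at most twice the final
#' subset size remains, elimination proceeds one feature at a time.  The
#' elimination order (last survivor first) defines the ranking; the top
#' `top_frac * G` features are exposed as an ordered subset.
#'
#' Duplicate columns receive adjacent ranks in column order (the fold
#' average breaks exact symmetry only through the fold draw).
#'
#' @inheritParams info_gain_rank
#' @param seed Seed controlling the fold assignment.
#' @param cost SVM cost parameter.
#' @return A [selector_output()] with `output_type = "ranking"`.
#' @export
svm_rfe_rank <- function(X, y, cfg = selector_config(), seed = 1L, cost = 1) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  if (min(table(y)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  G <- ncol(X)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0     # constant columns: no signal
  fold <- stratified_folds(y, cfg$cv_folds, seed)
  yf <- factor(y)
  k_final <- top_k(G, cfg$top_frac)

  remaining <- seq_len(G)
  elim_order <- integer(0)                     # worst first
  while (length(remaining) > 1L) {
    sc <- matrix(0, nrow = cfg$cv_folds, ncol = length(remaining))
    for (f in seq_len(cfg$cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) tr <- rep(TRUE, length(y))
      fit <- e1071::svm(Xs[tr, remaining, drop = FALSE], yf[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      w <- drop(crossprod(fit$coefs, fit$SV))
      w2 <- w^2
      s <- sum(w2)
      sc[f, ] <- if (s > 0) w2 / s else w2
    }
    score <- colMeans(sc)
    n_drop <- if (length(remaining) > 2L * k_final)
      max(1L, floor(cfg$rfe_step_frac * length(remaining))) else 1L
    n_drop <- min(n_drop, length(remaining) - 1L)
    drop_pos <- order(score, seq_along(score))[seq_len(n_drop)]
    ## eliminate worst-scored first within the chunk
    elim_order <- c(elim_order, remaining[drop_pos])
    remaining <- remaining[-drop_pos]
  }
  elim_order <- c(elim_order, remaining)
  ranking <- rev(elim_order)                   # best first
  ranks <- integer(G)
  ranks[ranking] <- seq_len(G)
  selector_output("svm_rfe", "ranking", G,
                  selected = ranking[seq_len(min(k_final, G))],
                  ranks = ranks)
}

#' Boruta-style shadow-feature selection
#'
#' Wrapper around random forests using the shadow-feature scheme: in
#' every iteration each undecided feature is paired with a row-shuffled
#' copy (its shadow), a random forest with permutation importance is
#' fitted on the augmented design, and a feature scores a "hit" when its
#' importance exceeds the maximum shadow importance.  Hit counts are
#' tested against Binomial(k, 1/2) with a two-sided test at
#' `boruta_alpha` per tail: features significantly above chance are
#' Confirmed, significantly below are Rejected (and dropped from later
#' iterations), the remainder stay Tentative until the iteration cap.
#' The selected subset contains the decisions listed in
#' `cfg$boruta_decision` (default Confirmed and Tentative).
#'
#' @inheritParams info_gain_rank
#' @param seed Seed for the shadow shuffles and forests.
#' @return A [selector_output()] with `output_type = "subset"` and an
#'   attribute `decision` (factor of per-feature final decisions).
#' @export
boruta_select <- function(X, y, cfg = selector_config(), seed = 1L) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  G <- ncol(X)
  yf <- factor(y)
  decision <- rep("Tentative", G)
  active <- seq_len(G)
  hits <- integer(G)
  iter_seeds <- derive_seeds(seed, cfg$boruta_max_runs)
  for (k in seq_len(cfg$boruta_max_runs)) {
    if (!length(active)) break
    set.seed(iter_seeds[k])
    Xa <- X[, active, drop = FALSE]
    shadow <- apply(Xa, 2L, sample)
    df <- as.data.frame(cbind(Xa, shadow))
    names(df) <- c(paste0("f", active), paste0("s", seq_along(active)))
    df$.y <- yf
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = cfg$num_trees,
                          importance = "permutation",
                          seed = iter_seeds[k], num.threads = 1L)
    imp <- fit$variable.importance
    real_imp <- imp[seq_along(active)]
    shadow_max <- max(imp[-seq_along(active)])
    hits[active] <- hits[active] + (real_imp > shadow_max)
    ## sequential two-sided binomial test on the hit counts
    p_up <- stats::pbinom(hits[active] - 1L, k, 0.5, lower.tail = FALSE)
    p_dn <- stats::pbinom(hits[active], k, 0.5)
    decision[active[p_up < cfg$boruta_alpha]] <- "Confirmed"
    decision[active[p_dn < cfg$boruta_alpha]] <- "Rejected"
    active <- which(decision == "Tentative")
  }
  sel <- which(decision %in% cfg$boruta_decision)
  out <- selector_output("boruta", "subset", G, selected = sel)
  attr(out, "decision") <- factor(decision,
                                  levels = c("Confirmed", "Tentative", "Rejected"))
  out
}

#' Vita-style cross-validated permutation importance selection
#'
#' Hold-out permutation importance: the samples are split into
#' `cv_folds` stratified folds; for each fold a random forest is grown on
#' the remaining folds and its permutation importance is evaluated on the
#' held-out fold only (so the importance estimate is not contaminated by
#' overfitting).  Fold importances are averaged.  An empirical null is
#' formed by mirroring the non-positive importance values about zero, and
#' a feature's p-value is the fraction of null values at least as large
#' as its importance; features with p-value less than or equal to
#' `vita_p_threshold` (default exactly 0, i.e. importance exceeding every
#' null value) form the subset.
#'
#' @inheritParams info_gain_rank
#' @param seed Seed for fold assignment and forests.
#' @return A [selector_output()] with `output_type = "subset"` and
#'   attributes `importance` and `p_value`.
#' @export
vita_select <- function(X, y, cfg = selector_config(), seed = 1L) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  G <- ncol(X)
  fold <- stratified_folds(y, cfg$cv_folds, seed)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(G))
  df$.y <- factor(y)
  fold_seeds <- derive_seeds(seed + 1L, cfg$cv_folds)
  imp <- matrix(NA_real_, cfg$cv_folds, G)
  for (f in seq_len(cfg$cv_folds)) {
    ## trees are grown on the in-fold samples (case weight 1); with
    ## holdout = TRUE ranger computes permutation importance on the
    ## held-out, zero-weight samples only
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = cfg$num_trees,
                          importance = "permutation",
                          case.weights = as.numeric(fold != f),
                          holdout = TRUE,
                          seed = fold_seeds[f], num.threads = 1L)
    imp[f, ] <- fit$variable.importance
  }
  v <- colMeans(imp)
  nonpos <- v[v <= 0]
  null_vals <- c(nonpos, -nonpos)
  pval <- if (length(null_vals))
    vapply(v, function(x) mean(null_vals >= x), numeric(1))
  else as.numeric(v <= 0)
  sel <- which(pval <= cfg$vita_p_threshold)
  out <- selector_output("vita", "subset", G, selected = sel)
  attr(out, "importance") <- v
  attr(out, "p_value") <- pval
  out
}

#' Lasso feature selection
#'
#' L1-penalized logistic regression over a fixed lambda grid; lambda is
#' chosen by cross-validated binomial deviance and the subset is the set
#' of features with nonzero coefficients at the chosen lambda.
#'
#' @inheritParams info_gain_rank
#' @param seed Seed controlling the cross-validation folds.
#' @return A [selector_output()] with `output_type = "subset"` and an
#'   attribute `lambda` (the chosen penalty).
#' @export
lasso_select <- function(X, y, cfg = selector_config(), seed = 1L) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  foldid <- stratified_folds(y, cfg$cv_folds, seed)
  ## the very long Table-style grid makes glmnet's internal interpolation
  ## warn about duplicated lambda values; these warnings are expected
  fit <- withCallingHandlers(
    glmnet::cv.glmnet(X, y, family = "binomial",
                      lambda = cfg$lasso_lambda,
                      foldid = foldid, type.measure = "deviance",
                      standardize = TRUE),
    warning = function(w) {
      if (grepl("collapsing to unique", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ## exact grid position (interpolation over the long grid is noisy)
  i <- which.min(abs(fit$glmnet.fit$lambda - fit$lambda.min))
  beta <- as.numeric(fit$glmnet.fit$beta[, i])
  out <- selector_output("lasso", "subset", ncol(X),
                         selected = which(beta != 0))
  attr(out, "lambda") <- fit$lambda.min
  out
}

#' Run a named set of base selectors
#'
#' Convenience wrapper used by the ensemble and the benchmark harness.
#'
#' @param X Feature matrix; `y` binary labels.
#' @param y Binary labels.
#' @param methods Character vector among `"info_gain"`, `"cfs"`,
#'   `"svm_rfe"`, `"boruta"`, `"vita"`, `"lasso"`.
#' @param cfg A [selector_config()].
#' @param seed Master seed; each selector gets a derived seed.
#' @return Named list of [selector_output()] objects.
#' @export
run_base_selectors <- function(X, y,
                               methods = c("info_gain", "svm_rfe",
                                           "vita", "boruta"),
                               cfg = selector_config(), seed = 1L) {
  methods <- match.arg(methods,
                       c("info_gain", "cfs", "svm_rfe", "boruta",
                         "vita", "lasso"),
                       several.ok = TRUE)
  seeds <- derive_seeds(seed, length(methods))
  out <- Map(function(m, s) {
    switch(m,
           info_gain = info_gain_rank(X, y, cfg),
           cfs       = cfs_select(X, y, cfg),
           svm_rfe   = svm_rfe_rank(X, y, cfg, seed = s),
           boruta    = boruta_select(X, y, cfg, seed = s),
           vita      = vita_select(X, y, cfg, seed = s),
           lasso     = lasso_select(X, y, cfg, seed = s))
  }, methods, seeds)
  names(out) <- methods
  out
}
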
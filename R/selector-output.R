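#' Standardized output of a base feature selector
#'
#' All base selectors return this common container so that their results
#' can be aggregated.  A selector reports either a subset of features
#' (unordered or ordered by importance) or a full ranking of all G
#' features; ranking selectors additionally expose their top fraction as
#' an ordered subset so that every selector contributes to the candidate
#' set.
#'
#' @param method Selector name.
#' @param output_type One of `"subset"`, `"ordered_subset"`, `"ranking"`.
#' @param G Total number of features scored.
#' @param selected Integer vector of selected feature indices (ordered by
#'   importance for `"ordered_subset"` and `"ranking"`).
#' @param ranks Integer vector of length `G` with values in `1..G`
#'   (ties allowed); required for `output_type = "ranking"`.
#' @return A `selector_output` object.
#' @export
selector_output <- function(method, output_type, G, selected = integer(),
                            ranks = NULL) {
  output_type <- match.arg(output_type, c("subset", "ordered_subset", "ranking"))
  G <- as.integer(G)
  selected <- as.integer(selected)
  if (anyDuplicated(selected))
    stop("selected indices must be unique", call. = FALSE)
  if (length(selected) && (min(selected) < 1L || max(selected) > G))
    stop("selected indices must lie in 1..G", call. = FALSE)
  if (output_type == "ranking") {
    if (is.null(ranks) || length(ranks) != G)
      stop("ranking output requires a rank vector of length G", call. = FALSE)
    ranks <- as.integer(ranks)
    if (min(ranks) < 1L || max(ranks) > G)
      stop("ranks must lie in 1..G", call. = FALSE)
  } else if (!is.null(ranks)) {
    stop("ranks are only meaningful for ranking output", call. = FALSE)
  }
  structure(list(method = method, output_type = output_type, G = G,
                 selected = selected, ranks = ranks),
            class = "selector_output")
}

#' @export
print.selector_output <- function(x, ...) {
  cat(sprintf("<selector_output> %s (%s), G = %d, %d feature(s) selected\n",
              x$method, x$output_type, x$G, length(x$selected)))
  invisible(x)
}

#' Convert a selector output to a full rank vector
#'
#' Subset outputs are converted by placing the selected features first
#' (tied at rank 1 for unordered subsets, or in their reported order for
#' ordered subsets) and all unselected features tied at rank `G`.
#' Ranking outputs pass through unchanged.
#'
#' @param out A [selector_output()].
#' @return Integer vector of length `G` with values in `1..G`.
#' @export
selector_ranks <- function(out) {
  stopifnot(inherits(out, "selector_output"))
  if (out$output_type == "ranking") return(out$ranks)
  r <- rep(out$G, out$G)
  if (length(out$selected)) {
    if (out$output_type == "subset") {
      r[out$selected] <- 1L
    } else {
      r[out$selected] <- seq_along(out$selected)
    }
  }
  as.integer(r)
}

#' Configuration shared by the base feature selectors
#'
#' Defaults follow the benchmark configuration: ranking selectors expose
#' their top `0.05 * G` features, cross-validated selectors use 5 folds,
#' Boruta-style screening keeps both Confirmed and Tentative features,
#' the permutation-importance (Vita-style) selector keeps features with
#' empirical p-value exactly 0, and the lasso is tuned over the grid
#' `10^seq(-10, 10, by = 0.1)`.
#'
#' @param top_frac Fraction of features exposed as the ordered subset by
#'   ranking selectors.
#' @param cv_folds Cross-validation folds for SVM-RFE, the Vita-style
#'   selector and the lasso.
#' @param boruta_decision Which final Boruta decisions count as selected.
#' @param boruta_max_runs Iteration cap for the shadow-feature scheme.
#' @param boruta_alpha Two-sided binomial test level per tail.
#' @param vita_p_threshold Empirical p-value threshold (inclusive).
#' @param lasso_lambda Lambda grid for the lasso (decreasing internally).
#' @param num_trees Random-forest size for Boruta/Vita-style selectors.
#' @param rfe_step_frac Fraction of remaining features dropped per
#'   SVM-RFE iteration during the fast phase.
#' @param ig_bins Number of equal-frequency bins used to discretize
#'   features for information gain.
#' @return A `selector_config` list.
#' @export
selector_config <- function(top_frac = 0.05,
                            cv_folds = 5L,
                            boruta_decision = c("Confirmed", "Tentative"),
                            boruta_max_runs = 100L,
                            boruta_alpha = 0.01,
                            vita_p_threshold = 0,
                            lasso_lambda = 10^seq(-10, 10, by = 0.1),
                            num_trees = 500L,
                            rfe_step_frac = 0.10,
                            ig_bins = 10L) {
  stopifnot(top_frac > 0, top_frac <= 1, cv_folds >= 2,
            all(boruta_decision %in% c("Confirmed", "Tentative")),
            boruta_max_runs >= 1, boruta_alpha > 0, boruta_alpha < 0.5,
            vita_p_threshold >= 0, vita_p_threshold < 1,
            all(lasso_lambda > 0), num_trees >= 1,
            rfe_step_frac > 0, rfe_step_frac < 1, ig_bins >= 2)
  structure(list(top_frac = top_frac, cv_folds = as.integer(cv_folds),
                 boruta_decision = boruta_decision,
                 boruta_max_runs = as.integer(boruta_max_runs),
                 boruta_alpha = boruta_alpha,
                 vita_p_threshold = vita_p_threshold,
                 lasso_lambda = sort(lasso_lambda, decreasing = TRUE),
                 num_trees = as.integer(num_trees),
                 rfe_step_frac = rfe_step_frac,
                 ig_bins = as.integer(ig_bins)),
            class = "selector_config")
}

## shared input validation for all selectors
check_xy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(X))
    stop("length of y must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0L, 1L)))
    stop("y must be binary (0/1)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("y is constant: both classes must be present", call. = FALSE)
  list(X = X, y = y)
}

## number of features a ranking selector exposes as its ordered subset
top_k <- function(G, top_frac) max(1L, ceiling(top_frac * G))

## stratified fold assignment, seeded; returns integer fold id per sample
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
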
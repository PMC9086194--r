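#' Selection-quality metrics against known causal features
#'
#' FDR is the fraction of selected features that are non-causal (0 when
#' nothing is selected), sensitivity the fraction of causal features
#' recovered, precision `1 - FDR`, and F1 the harmonic mean
#' `2 * precision * sensitivity / (precision + sensitivity)` (0 when
#' both terms are 0).
#'
#' @param selected Integer vector of selected feature indices.
#' @param causal Integer vector of causal feature indices (nonempty).
#' @param G Total feature count.
#' @return List with `fdr`, `sensitivity`, `precision`, `f1`,
#'   `n_selected`.
#' @export
selection_metrics <- function(selected, causal, G) {
  selected <- as.integer(selected); causal <- as.integer(causal)
  stopifnot(length(causal) >= 1L)
  if (length(selected) && (min(selected) < 1L || max(selected) > G))
    stop("selected indices out of 1..G", call. = FALSE)
  if (length(selected) == 0L)
    return(list(fdr = 0, sensitivity = 0, precision = 1, f1 = 0,
                n_selected = 0L))
  fp <- length(setdiff(selected, causal))
  fdr <- fp / length(selected)
  sens <- length(intersect(selected, causal)) / length(causal)
  prec <- 1 - fdr
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(fdr = fdr, sensitivity = sens, precision = prec, f1 = f1,
       n_selected = length(selected))
}

#' Jaccard stability of paired selections
#'
#' For each pair of selected sets, the Jaccard index
#' `|A intersect B| / |A union B|` (defined as 1 when both sets are
#' empty); the mean across pairs quantifies selection stability.
#'
#' @param pairs List of 2-element lists/vectors of feature index sets.
#' @return List with `jaccard` (per pair) and `mean`.
#' @export
jaccard_stability <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  j <- vapply(pairs, function(p) {
    A <- unique(as.integer(p[[1]])); B <- unique(as.integer(p[[2]]))
    u <- length(union(A, B))
    if (u == 0L) 1 else length(intersect(A, B)) / u
  }, numeric(1))
  list(jaccard = j, mean = mean(j))
}

#' Empirical power of causal variables
#'
#' Per causal variable, the fraction of replicates in which it was
#' selected.
#'
#' @param selections List of selected index sets, one per replicate.
#' @param causal Integer vector of causal feature indices.
#' @return Named numeric vector of selection frequencies (names are the
#'   causal indices).
#' @export
empirical_power <- function(selections, causal) {
  stopifnot(length(selections) >= 1L, length(causal) >= 1L)
  freq <- vapply(causal, function(v)
    mean(vapply(selections, function(s) v %in% s, logical(1))), numeric(1))
  names(freq) <- as.character(causal)
  freq
}

#' Weighted relative frequency of selection across folds
#'
#' `WRF_j = sum over folds f of I{j in S_f} / |S_f|`: each fold
#' distributes one unit of mass uniformly over the features it selected,
#' so a feature's WRF rewards membership in small (confident) selections.
#' Empty folds contribute 0.
#'
#' @param fold_selections List of selected feature sets, one per fold
#'   (integer indices or character names).
#' @param features Optional universe of features to report; defaults to
#'   the union of the fold selections.
#' @return Named numeric vector of WRF values.
#' @export
weighted_relative_frequency <- function(fold_selections, features = NULL) {
  stopifnot(length(fold_selections) >= 1L)
  if (is.null(features))
    features <- sort(unique(unlist(fold_selections)))
  wrf <- stats::setNames(rep(0, length(features)), as.character(features))
  for (S in fold_selections) {
    if (!length(S)) next
    S <- as.character(unique(S))
    hit <- as.character(features) %in% S
    wrf[hit] <- wrf[hit] + 1 / length(S)
  }
  wrf
}
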
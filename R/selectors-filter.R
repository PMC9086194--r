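#' Information-gain feature ranking
#'
#' Univariate filter: each feature is discretized into equal-frequency
#' bins and scored by the mutual information between the binned feature
#' and the class label, `IG = H(y) - H(y | bin)`.  Features are ranked by
#' decreasing gain; the top `top_frac * G` are also exposed as an ordered
#' subset.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels.
#' @param cfg A [selector_config()].
#' @return A [selector_output()] with `output_type = "ranking"`.
#' @export
info_gain_rank <- function(X, y, cfg = selector_config()) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  gains <- apply(X, 2L, function(x) info_gain_one(x, y, cfg$ig_bins))
  ranks <- rank(-gains, ties.method = "min")
  ord <- order(-gains, seq_along(gains))   # gain desc, index for ties
  k <- top_k(ncol(X), cfg$top_frac)
  selector_output("info_gain", "ranking", ncol(X),
                  selected = ord[seq_len(min(k, ncol(X)))],
                  ranks = ranks)
}

## entropy of a discrete distribution given counts, in nats
entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

info_gain_one <- function(x, y, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE))
  if (length(br) < 2L) return(0)          # constant feature carries no signal
  b <- cut(x, breaks = br, include.lowest = TRUE)
  hy <- entropy_counts(table(y))
  tab <- table(b, y)
  nb <- rowSums(tab)
  hcond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    (nb[i] / length(y)) * entropy_counts(tab[i, ])
  }, numeric(1)))
  hy - hcond
}

#' Correlation-based feature selection (CFS)
#'
#' Multivariate filter: best-first search over feature subsets maximizing
#' the merit
#' `k * mean|cor(f, y)| / sqrt(k + k (k - 1) * mean|cor(f, f')|)`,
#' which rewards features correlated with the class and penalizes
#' redundancy among the chosen features.  The search expands the best
#' open subset by one feature at a time and stops after `stale`
#' consecutive non-improving expansions.
#'
#' @inheritParams info_gain_rank
#' @param stale Consecutive non-improving expansions tolerated before the
#'   search stops.
#' @return A [selector_output()] with `output_type = "subset"`.
#' @export
cfs_select <- function(X, y, cfg = selector_config(), stale = 5L) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  G <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  usable <- which(sds > 0)
  if (length(usable) < G)
    warning("skipping ", G - length(usable), " zero-variance feature(s)")
  if (!length(usable))
    return(selector_output("cfs", "subset", G, integer()))
  rcy <- abs(suppressWarnings(stats::cor(X[, usable, drop = FALSE], y)))[, 1]
  rcc <- abs(suppressWarnings(stats::cor(X[, usable, drop = FALSE])))

  merit <- function(S) {
    k <- length(S)
    if (k == 0L) return(0)
    num <- k * mean(rcy[S])
    den <- sqrt(k + k * (k - 1) * mean_offdiag(rcc, S))
    num / den
  }

  best_S <- integer(); best_m <- 0
  frontier <- list(integer())
  frontier_m <- 0
  n_stale <- 0L
  while (n_stale < stale && length(frontier)) {
    i_best <- which.max(frontier_m)
    S <- frontier[[i_best]]
    frontier <- frontier[-i_best]; frontier_m <- frontier_m[-i_best]
    cand <- setdiff(seq_along(usable), S)
    improved <- FALSE
    for (f in cand) {
      S2 <- c(S, f)
      m2 <- merit(S2)
      frontier <- c(frontier, list(S2)); frontier_m <- c(frontier_m, m2)
      if (m2 > best_m + 1e-12) {
        best_m <- m2; best_S <- S2; improved <- TRUE
      }
    }
    n_stale <- if (improved) 0L else n_stale + 1L
    ## keep the frontier bounded: retain the best 50 open nodes
    if (length(frontier) > 50L) {
      keep <- order(frontier_m, decreasing = TRUE)[1:50]
      frontier <- frontier[keep]; frontier_m <- frontier_m[keep]
    }
  }
  selector_output("cfs", "subset", G, selected = sort(usable[best_S]))
}

mean_offdiag <- function(M, S) {
  k <- length(S)
  if (k < 2L) return(0)
  sub <- M[S, S, drop = FALSE]
  (sum(sub) - k) / (k * (k - 1))
}
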
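#' Aggregate base-selector outputs into best-position ranks
#'
#' Every selector output is converted to a full rank vector (subset
#' selectors: selected features tied at rank 1, or in reported order for
#' ordered subsets; unselected features tied at rank G) and the
#' aggregated rank of a feature is the best (minimum) position it
#' achieved across selectors.  The union of the selectors' selected sets
#' forms the base candidate set.
#'
#' @param outputs List of [selector_output()] objects sharing `G`.
#' @return A `rank_aggregation` object: `agg_rank` (length G),
#'   `rank_matrix` (selectors x G), `base_selected` (sorted union of
#'   selected indices), `G`.
#' @export
aggregate_ranks <- function(outputs) {
  stopifnot(length(outputs) >= 1L,
            all(vapply(outputs, inherits, logical(1), "selector_output")))
  Gs <- vapply(outputs, `[[`, integer(1), "G")
  if (length(unique(Gs)) != 1L)
    stop("all selector outputs must score the same number of features",
         call. = FALSE)
  G <- Gs[1]
  rk <- t(vapply(outputs, selector_ranks, integer(G)))
  rownames(rk) <- vapply(outputs, `[[`, character(1), "method")
  structure(list(
    agg_rank = apply(rk, 2L, min),
    rank_matrix = rk,
    base_selected = sort(unique(unlist(lapply(outputs, `[[`, "selected")))),
    G = G
  ), class = "rank_aggregation")
}

#' Expand the candidate set by correlation
#'
#' Adds to the base-selected set every feature whose absolute sample
#' correlation with some base-selected feature exceeds `rho`.  The
#' expansion is a single pass (direct neighbours only, no transitive
#' closure).  Zero-variance features have undefined correlations, which
#' are treated as 0.
#'
#' @param agg A `rank_aggregation`.
#' @param X Full feature matrix the ranks refer to.
#' @param rho Correlation threshold in (0, 1).
#' @return The input `agg` with fields `candidates` (sorted indices) and
#'   `expanded` (logical per candidate: entered via correlation only).
#' @export
expand_candidates <- function(agg, X, rho = 0.75) {
  stopifnot(inherits(agg, "rank_aggregation"), ncol(X) == agg$G,
            rho > 0, rho < 1)
  base <- agg$base_selected
  if (!length(base))
    stop("base candidate set is empty", call. = FALSE)
  others <- setdiff(seq_len(agg$G), base)
  extra <- integer()
  if (length(others)) {
    cc <- suppressWarnings(
      stats::cor(X[, others, drop = FALSE], X[, base, drop = FALSE]))
    cc[is.na(cc)] <- 0
    extra <- others[apply(abs(cc) > rho, 1L, any)]
  }
  cand <- sort(c(base, extra))
  agg$candidates <- cand
  agg$expanded <- !(cand %in% base)
  agg$rho <- rho
  agg
}

#' Partition candidate features into correlation blocks
#'
#' Complete-linkage agglomerative clustering on distance
#' `1 - |correlation|`, cut just below height `1 - rho`, which guarantees
#' that within every block all pairwise absolute correlations exceed
#' `rho`.  The block penalty weight is
#' `s_b = (minimum aggregated rank among block members) * sqrt(L_b)`,
#' where `L_b` is the block size and `sqrt(L_b)` is the standard
#' group-lasso size factor (it keeps the entry value of a coherent
#' block comparable to a single feature carrying the same per-feature
#' signal); members that entered the candidate set only through
#' correlation expansion contribute rank `G` to the minimum.
#'
#' @param agg A `rank_aggregation` carrying `candidates` (see
#'   [expand_candidates()]).
#' @param X Full feature matrix.
#' @param rho Correlation threshold (defaults to the one used for
#'   expansion).
#' @return A `block_partition` object: `candidates`, `block` (id per
#'   candidate), `B`, `sizes`, `sb`, `rho`, `member_rank`.
#' @export
form_blocks <- function(agg, X, rho = agg$rho) {
  stopifnot(inherits(agg, "rank_aggregation"), !is.null(agg$candidates))
  cand <- agg$candidates
  p <- length(cand)
  if (p == 1L) {
    blk <- 1L
  } else {
    cc <- suppressWarnings(stats::cor(X[, cand, drop = FALSE]))
    cc[is.na(cc)] <- 0
    d <- stats::as.dist(1 - abs(cc))
    tree <- stats::hclust(d, method = "complete")
    blk <- stats::cutree(tree, h = (1 - rho) - 1e-9)
  }
  B <- max(blk)
  ## rank used for weighting: aggregated rank, but expansion-only
  ## members count as rank G (they were not picked by any selector)
  wrank <- agg$agg_rank[cand]
  wrank[agg$expanded] <- agg$G
  sizes <- tabulate(blk, B)
  sb <- vapply(seq_len(B), function(b)
    min(wrank[blk == b]) * sqrt(sizes[b]), numeric(1))
  structure(list(candidates = cand, block = blk, B = B, sizes = sizes,
                 sb = sb, rho = rho, member_rank = wrank),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d candidate(s) in %d block(s), rho = %g\n",
              length(x$candidates), x$B, x$rho))
  cat(sprintf("  block sizes: %s\n", paste(x$sizes, collapse = " ")))
  invisible(x)
}

#' One permutation-assisted group-lasso selection round
#'
#' Draws a seeded row permutation, appends the permuted candidate matrix
#' as pseudo-variables (one pseudo block mirroring each original block,
#' with the same penalty weight), fits the group-lasso path on the
#' augmented design, and records each block's entry value `R_b`.  The
#' benchmark `T_pi` is the largest pseudo-block entry value; the round
#' selects the original blocks with `R_b` strictly greater than `T_pi`.
#'
#' Entry values are read off the lambda grid, so two blocks entering
#' within the same grid interval are recorded with identical values.
#' When an original block is tied exactly with `T_pi`, the tie is
#' resolved by bisection refinement ([refine_entry_value()]) of the
#' tied blocks; a tie that survives refinement still loses (strict
#' inequality).
#'
#' @param Xc Standardized candidate matrix (n x p).
#' @param y Binary 0/1 labels.
#' @param part A `block_partition` over the p candidates.
#' @param seed Seed for the row permutation.
#' @param ... Passed to [fit_group_lasso_path()].
#' @return List: `selected` (original block ids), `T_pi`, `R_orig`,
#'   `R_pseudo`, `perm`, `path`.
#' @export
permutation_select_once <- function(Xc, y, part, seed, ...) {
  stopifnot(inherits(part, "block_partition"),
            ncol(Xc) == length(part$candidates))
  set.seed(as.integer(seed))
  perm <- sample(nrow(Xc))
  XA <- cbind(Xc, Xc[perm, , drop = FALSE])
  blocks_A <- c(part$block, part$block + part$B)
  sb_A <- c(part$sb, part$sb)
  path <- fit_group_lasso_path(XA, y, blocks_A, sb_A, ...)
  R_orig <- path$R[seq_len(part$B)]
  R_pseudo <- path$R[part$B + seq_len(part$B)]
  T_pi <- max(R_pseudo)
  ## grid ties between an original block and the benchmark are
  ## quantization artefacts: both entered in the same lambda interval.
  ## Refine exactly the tied blocks (only pseudo blocks at the same grid
  ## position can move the benchmark within that interval).
  tied <- which(R_orig == T_pi & R_orig > 0)
  if (length(tied) && T_pi > 0) {
    ref_orig <- vapply(tied, function(b)
      refine_entry_value(XA, y, blocks_A, sb_A, path, b), numeric(1))
    tied_pseudo <- which(R_pseudo == T_pi)
    ref_pseudo <- vapply(tied_pseudo, function(b)
      refine_entry_value(XA, y, blocks_A, sb_A, path, part$B + b),
      numeric(1))
    T_cmp <- max(ref_pseudo)
    selected <- which(R_orig > T_pi | seq_len(part$B) %in%
                        tied[ref_orig > T_cmp])
  } else {
    selected <- which(R_orig > T_pi)
  }
  list(selected = selected, T_pi = T_pi,
       R_orig = R_orig, R_pseudo = R_pseudo, perm = perm, path = path)
}

#' Ensemble feature selection with permutation-assisted group lasso
#'
#' The full pipeline: run (or accept) base selectors, aggregate their
#' outputs into best-position ranks, expand the selected set with
#' correlated features, partition the candidates into correlation
#' blocks, and screen the blocks with a group-lasso logistic model tuned
#' against row-permuted pseudo-variables.  The permutation round is
#' repeated `K` times and the final selection keeps the blocks chosen in
#' at least a fraction `tau` of the rounds.
#'
#' With `standalone = TRUE` no base selectors are used: the candidate
#' set is all features and every feature carries the same rank, so the
#' method acts as an independent feature selector.
#'
#' @param X Feature matrix (samples x features).
#' @param y Binary 0/1 labels.
#' @param base_outputs Optional precomputed list of [selector_output()];
#'   when `NULL`, the selectors in `methods` are run internally.
#' @param methods Base selectors to run (see [run_base_selectors()]).
#' @param rho Within-block correlation threshold (default 0.75).
#' @param K Number of permutation rounds (default 50).
#' @param tau Selection-frequency threshold in (0, 1] (default 0.5; a
#'   block is kept when selected in `>= tau * K` rounds).
#' @param seed Master seed; selector, permutation and fold seeds are
#'   derived from it.
#' @param cfg A [selector_config()] for internally run selectors.
#' @param standalone Use all features with constant rank instead of base
#'   selectors.
#' @param ... Passed to [fit_group_lasso_path()].
#' @return A `repsel_ensemble` object: `selected` (final feature
#'   indices), `selected_blocks`, `block_frequency`, `T_pi` (length K),
#'   `per_round` (list of per-round block sets), `partition`,
#'   `aggregation`, `config`.
#' @export
ensemble_select <- function(X, y, base_outputs = NULL,
                            methods = c("info_gain", "svm_rfe",
                                        "vita", "boruta"),
                            rho = 0.75, K = 50L, tau = 0.5, seed = 1L,
                            cfg = selector_config(), standalone = FALSE,
                            ...) {
  d <- check_xy(X, y); X <- d$X; y <- d$y
  stopifnot(rho > 0, rho < 1, K >= 1, tau > 0, tau <= 1)
  seeds <- derive_seeds(seed, K + 1L)
  if (standalone) {
    agg <- structure(list(
      agg_rank = rep(1L, ncol(X)),
      rank_matrix = matrix(1L, 1L, ncol(X),
                           dimnames = list("constant", NULL)),
      base_selected = seq_len(ncol(X)), G = ncol(X)
    ), class = "rank_aggregation")
    agg$candidates <- seq_len(ncol(X))
    agg$expanded <- rep(FALSE, ncol(X))
    agg$rho <- rho
  } else {
    if (is.null(base_outputs))
      base_outputs <- run_base_selectors(X, y, methods, cfg,
                                         seed = seeds[K + 1L])
    agg <- aggregate_ranks(base_outputs)
    if (!length(agg$base_selected)) {
      warning("no base selector selected any feature; empty result")
      return(empty_ensemble_result(K, tau, seed))
    }
    agg <- expand_candidates(agg, X, rho)
  }
  part <- form_blocks(agg, X, rho)
  Xc <- scale(X[, agg$candidates, drop = FALSE])
  Xc[, attr(Xc, "scaled:scale") == 0] <- 0
  rounds <- lapply(seq_len(K), function(k)
    permutation_select_once(Xc, y, part, seed = seeds[k], ...))
  sel_sets <- lapply(rounds, `[[`, "selected")
  freq <- tabulate(unlist(sel_sets), part$B) / K
  final_blocks <- which(freq >= tau)
  final_feats <- sort(part$candidates[part$block %in% final_blocks])
  structure(list(selected = final_feats, selected_blocks = final_blocks,
                 block_frequency = freq,
                 T_pi = vapply(rounds, `[[`, numeric(1), "T_pi"),
                 per_round = sel_sets,
                 partition = part, aggregation = agg,
                 config = list(rho = rho, K = K, tau = tau, seed = seed,
                               standalone = standalone,
                               methods = if (is.null(base_outputs)) methods
                                         else vapply(base_outputs, `[[`,
                                                     character(1), "method"))),
            class = "repsel_ensemble")
}

empty_ensemble_result <- function(K, tau, seed) {
  structure(list(selected = integer(), selected_blocks = integer(),
                 block_frequency = numeric(), T_pi = numeric(),
                 per_round = list(), partition = NULL, aggregation = NULL,
                 config = list(K = K, tau = tau, seed = seed)),
            class = "repsel_ensemble")
}

#' @export
print.repsel_ensemble <- function(x, ...) {
  cat("<repsel_ensemble>\n")
  if (is.null(x$partition)) {
    cat("  empty candidate set; nothing selected\n")
    return(invisible(x))
  }
  cat(sprintf("  %d candidate(s) in %d block(s); K = %d, tau = %g\n",
              length(x$partition$candidates), x$partition$B,
              x$config$K, x$config$tau))
  cat(sprintf("  selected %d block(s) / %d feature(s)\n",
              length(x$selected_blocks), length(x$selected)))
  if (length(x$selected))
    cat("  features:", paste(utils::head(x$selected, 20), collapse = " "),
        if (length(x$selected) > 20) "..." else "", "\n")
  invisible(x)
}
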
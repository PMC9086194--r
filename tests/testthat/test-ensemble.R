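# correlated-group fixture for block formation: k groups of m near-copies
make_grouped_X <- function(n, k, m, seed, noise = 0.1) {
  set.seed(seed)
  base <- matrix(runif(n * k), n, k)
  X <- do.call(cbind, lapply(seq_len(k), function(i)
    base[, i] + matrix(rnorm(n * m, sd = noise), n, m)))
  X
}

test_that("rank aggregation takes the best position across selectors", {
  # a feature ranked 1st by one selector and 10th by another records 1st
  r1 <- selector_output("a", "ranking", 10, selected = 1:2,
                        ranks = c(1L, 2:10))
  r2 <- selector_output("b", "ranking", 10, selected = 10:9,
                        ranks = c(10L, 9L, 8:2, 1L))
  agg <- aggregate_ranks(list(r1, r2))
  expect_equal(agg$agg_rank[1], 1)
  # subset selectors: unselected features are tied at rank G
  s <- selector_output("c", "subset", 10, selected = c(3L, 7L))
  agg2 <- aggregate_ranks(list(s))
  expect_equal(agg2$agg_rank[c(3, 7)], c(1, 1))
  expect_equal(agg2$agg_rank[c(1, 2, 4)], c(10, 10, 10))
  # brute-force elementwise minimum over three mixed outputs
  outs <- list(random_selector_output(8, "subset", 1),
               random_selector_output(8, "ordered_subset", 2),
               random_selector_output(8, "ranking", 3))
  agg3 <- aggregate_ranks(outs)
  manual <- apply(do.call(rbind, lapply(outs, selector_ranks)), 2, min)
  expect_equal(agg3$agg_rank, manual)
  expect_true(all(agg3$agg_rank <= t(agg3$rank_matrix)))
  expect_true(all(unlist(lapply(outs, `[[`, "selected")) %in%
                    agg3$base_selected))
  expect_error(aggregate_ranks(list(r1, random_selector_output(5, "subset", 4))),
               "same number")
})

test_that("aggregated rank minimality holds on random selector outputs", {
  for (seed in 1:8) {
    outs <- lapply(seq_len(3 + seed %% 3), function(i)
      random_selector_output(12, c("subset", "ordered_subset", "ranking")[1 + (i + seed) %% 3],
                             seed * 10 + i))
    agg <- aggregate_ranks(outs)
    for (o in outs)
      expect_true(all(agg$agg_rank <= selector_ranks(o)))
  }
})

test_that("candidate expansion adds exactly the correlated neighbours", {
  set.seed(5)
  X <- matrix(runif(200), 40, 5)
  X <- cbind(X, X[, 2])                       # column 6 duplicates column 2
  out <- selector_output("s", "subset", 6, selected = 2L)
  agg <- aggregate_ranks(list(out))
  agg <- expand_candidates(agg, X, rho = 0.75)
  expect_setequal(agg$candidates, c(2L, 6L))
  expect_equal(agg$expanded, c(FALSE, TRUE))
  # uncorrelated noise: candidate set stays the base set
  out2 <- selector_output("s", "subset", 5, selected = 3L)
  agg2 <- expand_candidates(aggregate_ranks(list(out2)), X[, 1:5], 0.75)
  expect_equal(agg2$candidates, 3L)
  expect_error(expand_candidates(aggregate_ranks(list(
    selector_output("s", "subset", 5))), X[, 1:5], 0.75), "empty")
})

test_that("blocks satisfy the all-pairs correlation property", {
  X <- make_grouped_X(n = 60, k = 4, m = 3, seed = 9)
  out <- selector_output("s", "subset", 12, selected = 1:12)
  agg <- expand_candidates(aggregate_ranks(list(out)), X, 0.75)
  part <- form_blocks(agg, X)
  cc <- abs(stats::cor(X))
  for (b in seq_len(part$B)) {
    mem <- part$candidates[part$block == b]
    if (length(mem) > 1)
      expect_gt(min(cc[mem, mem]), 0.75)
  }
  expect_equal(sum(part$sizes), 12L)
  # penalty weights: min member rank times sqrt(block size)
  expect_equal(part$sb,
               vapply(seq_len(part$B), function(b)
                 min(part$member_rank[part$block == b]) *
                   sqrt(part$sizes[b]), numeric(1)))
  # mutually uncorrelated candidates -> all singletons
  set.seed(10)
  Xu <- matrix(rnorm(60 * 6), 60, 6)
  aggu <- aggregate_ranks(list(selector_output("s", "subset", 6,
                                               selected = 1:6)))
  aggu <- expand_candidates(aggu, Xu, 0.75)
  pu <- form_blocks(aggu, Xu)
  expect_equal(pu$B, 6L)
  expect_equal(pu$sizes, rep(1L, 6L))
  # three identical columns form one block
  Xi <- cbind(Xu[, 1], Xu[, 1], Xu[, 1])
  aggi <- expand_candidates(aggregate_ranks(list(
    selector_output("s", "subset", 3, selected = 1L))), Xi, 0.75)
  pi_ <- form_blocks(aggi, Xi)
  expect_equal(pi_$B, 1L)
  expect_equal(pi_$sizes, 3L)
})

test_that("the null model holds at the top of the lambda grid", {
  set.seed(20)
  n <- 50
  X <- scale(matrix(rnorm(n * 6), n, 6))
  y <- rbinom(n, 1, 0.6)
  path <- fit_group_lasso_path(X, y, blocks = rep(1:3, each = 2),
                               sb = rep(1, 3))
  expect_equal(max(abs(path$beta[, 1])), 0)
  expect_equal(path$beta0[1], qlogis(mean(y)), tolerance = 1e-3)
  # entry values live on the grid (or are 0)
  expect_true(all(path$R %in% c(0, path$lambda)))
  # a block with an enormous weight never enters
  path2 <- fit_group_lasso_path(X, y, blocks = c(rep(1L, 2), rep(2L, 4)),
                                sb = c(1e8, 1))
  expect_equal(path2$R[1], 0)
})

test_that("path coefficients match an independent FISTA solver", {
  set.seed(33)
  n <- 40
  blocks <- rep(1:3, each = 3)
  X <- scale(make_grouped_X(n, 3, 3, seed = 33, noise = 0.3))
  eta <- 1.2 * X[, 1] - 0.8 * X[, 4]
  y <- rbinom(n, 1, plogis(eta))
  sb <- c(1, 2, 1) * sqrt(3)
  path <- fit_group_lasso_path(X, y, blocks, sb, tol = 1e-9,
                               max_sweeps = 20000L, fdev = 0,
                               dev_ratio_max = 1, n_lambda = 70L,
                               lambda_min_ratio = 0.01)
  probe <- round(seq(5, 60, length.out = 5))
  for (i in probe) {
    lam <- path$lambda[i]
    ref <- fista_group_lasso(X, y, blocks, sb, lam)
    expect_equal(path$beta[, i], ref$beta, tolerance = 1e-4,
                 label = sprintf("coefficients at lambda %.3g", lam))
    expect_equal(path$beta0[i], ref$beta0, tolerance = 1e-4)
    # and the objective is no worse than the reference's
    q_pkg <- group_lasso_objective(X, y, path$beta0[i], path$beta[, i],
                                   blocks, sb, lam)
    q_ref <- group_lasso_objective(X, y, ref$beta0, ref$beta, blocks, sb, lam)
    expect_lt(q_pkg, q_ref + 1e-6)
  }
})

test_that("a perfectly predictive block survives every permutation round", {
  set.seed(40)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  sig <- as.numeric(y) + rnorm(n, sd = 0.01)
  X <- cbind(sig, sig + rnorm(n, sd = 0.01), matrix(rnorm(n * 3), n, 3))
  out <- selector_output("s", "subset", 5, selected = c(1L, 2L))
  agg <- expand_candidates(aggregate_ranks(list(out)), X, 0.75)
  part <- form_blocks(agg, X)
  Xc <- scale(X[, agg$candidates, drop = FALSE])
  sig_block <- part$block[part$candidates == 1L]
  for (s in 1:5) {
    r <- permutation_select_once(Xc, y, part, seed = s)
    expect_true(sig_block %in% r$selected)
  }
})

test_that("original and pseudo entry values are exchangeable under the null", {
  set.seed(50)
  n <- 40
  X <- make_grouped_X(n, 3, 2, seed = 50, noise = 0.2)
  out <- selector_output("s", "subset", 6, selected = 1:6)
  agg <- expand_candidates(aggregate_ranks(list(out)), X, 0.75)
  part <- form_blocks(agg, X)
  Xc <- scale(X)
  R_o <- c(); R_p <- c()
  for (s in 1:60) {
    set.seed(s * 7)
    y <- rbinom(n, 1, 0.5)           # independent of X
    if (length(unique(y)) < 2) next
    r <- permutation_select_once(Xc, y, part, seed = s)
    R_o <- c(R_o, r$R_orig); R_p <- c(R_p, r$R_pseudo)
  }
  w <- stats::wilcox.test(R_o, R_p, exact = FALSE)
  expect_gt(w$p.value, 0.01)
})

test_that("ensemble selection is deterministic and respects K and tau", {
  sc <- simulation_scenario("mini", n = 60L, G = 40L, eta = 0.5,
                            beta = c(0, -9, 6, 3), group_sizes = rep(5L, 6L))
  sim <- simulate_dataset(sc, seed = 60)
  cfg <- selector_config(num_trees = 150L, boruta_max_runs = 40L)
  e1 <- suppressWarnings(ensemble_select(sim$X, sim$y, K = 8L, seed = 61,
                                         cfg = cfg))
  e2 <- suppressWarnings(ensemble_select(sim$X, sim$y, K = 8L, seed = 61,
                                         cfg = cfg))
  expect_identical(e1[names(e1) != "per_round"], e2[names(e2) != "per_round"])
  expect_identical(e1$per_round, e2$per_round)
  # frequencies tally with the per-round sets; tau >= rule is inclusive
  freq <- tabulate(unlist(e1$per_round), e1$partition$B) / 8
  expect_equal(freq, e1$block_frequency)
  expect_setequal(e1$selected_blocks, which(freq >= 0.5))
  # with K = 1 and tau <= 1, the final set is that round's members
  e3 <- suppressWarnings(ensemble_select(sim$X, sim$y,
                                         base_outputs = list(
                                           info_gain_rank(sim$X, sim$y, cfg)),
                                         K = 1L, seed = 62, cfg = cfg))
  want <- sort(e3$partition$candidates[e3$partition$block %in%
                                         e3$per_round[[1]]])
  expect_equal(e3$selected, want)
})

test_that("standalone mode uses all features with constant rank", {
  set.seed(70)
  n <- 50
  y <- rep(c(0L, 1L), 25)
  X <- cbind(as.numeric(y) + rnorm(n, sd = 0.2), matrix(runif(n * 9), n, 9))
  e <- ensemble_select(X, y, standalone = TRUE, K = 5L, seed = 71)
  expect_equal(length(e$aggregation$candidates), 10L)
  expect_true(all(e$aggregation$agg_rank == 1))
  expect_true(1L %in% e$selected)
})

test_that("grid entry values agree with bisection-refined ones", {
  # decision agreement on small random instances
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 50
    X <- make_grouped_X(n, 2, 2, seed = 100 + s, noise = 0.3)
    X <- cbind(X, matrix(runif(n * 2), n, 2))
    eta <- 2 * scale(X[, 1])
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    out <- selector_output("s", "subset", 6, selected = 1:6)
    agg <- expand_candidates(aggregate_ranks(list(out)), X, 0.75)
    part <- form_blocks(agg, X)
    Xc <- scale(X)
    r <- permutation_select_once(Xc, y, part, seed = s)
    blocks_A <- c(part$block, part$block + part$B)
    sb_A <- c(part$sb, part$sb)
    set.seed(s); perm <- sample(n)
    XA <- cbind(Xc, Xc[perm, ])
    refined <- vapply(seq_len(2 * part$B), function(b)
      refine_entry_value(XA, y, blocks_A, sb_A, r$path, b), numeric(1))
    T_ref <- max(refined[part$B + seq_len(part$B)])
    sel_ref <- which(refined[seq_len(part$B)] > T_ref)
    expect_equal(r$selected, sel_ref,
                 label = sprintf("instance %d decisions", s))
  }
})
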
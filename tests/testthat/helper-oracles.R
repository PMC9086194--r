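# Independent reference implementations used as oracles.  These are
# deliberately written with different algorithms from the package code
# they check.

# Accelerated proximal-gradient (FISTA) solver for the group-lasso
# logistic objective -loglik + lambda * sum_b s_b ||beta_b||, intercept
# unpenalized.  Full-gradient method with a global Lipschitz constant --
# independent of the package's blockwise coordinate descent.
fista_group_lasso <- function(X, y, blocks, sb, lambda,
                              iters = 50000, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  L <- max(eigen(crossprod(Xi), symmetric = TRUE,
                 only.values = TRUE)$values) / 4
  beta <- rep(0, p + 1L)
  z <- beta; tprev <- 1
  obj <- function(b) {
    eta <- drop(Xi %*% b)
    -sum(y * eta - log1p(exp(eta))) +
      lambda * sum(vapply(seq_len(max(blocks)), function(g)
        sb[g] * sqrt(sum(b[-1][blocks == g]^2)), numeric(1)))
  }
  o_prev <- obj(beta)
  for (it in seq_len(iters)) {
    eta <- drop(Xi %*% z)
    g <- -drop(crossprod(Xi, y - stats::plogis(eta)))
    v <- z - g / L
    b_new <- v
    for (gb in seq_len(max(blocks))) {
      idx <- which(blocks == gb) + 1L
      nb <- sqrt(sum(v[idx]^2))
      thr <- lambda * sb[gb] / L
      b_new[idx] <- if (nb <= thr) 0 else (1 - thr / nb) * v[idx]
    }
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    z <- b_new + ((tprev - 1) / tnew) * (b_new - beta)
    beta <- b_new; tprev <- tnew
    if (it %% 200 == 0) {
      o <- obj(beta)
      if (abs(o_prev - o) < tol * (1 + abs(o))) break
      o_prev <- o
    }
  }
  list(beta0 = beta[1], beta = beta[-1])
}

# Direct entropy-sum information gain on prebinned data.
entropy_oracle <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

info_gain_oracle <- function(x, y, bins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE))
  if (length(br) < 2L) return(0)
  b <- as.integer(cut(x, breaks = br, include.lowest = TRUE))
  hy <- entropy_oracle(table(y))
  hcond <- 0
  for (lev in unique(b)) {
    idx <- b == lev
    hcond <- hcond + mean(idx) * entropy_oracle(table(y[idx]))
  }
  hy - hcond
}

# CFS merit computed from scratch for an explicit subset.
cfs_merit_oracle <- function(X, y, S) {
  k <- length(S)
  if (k == 0) return(0)
  rcy <- abs(stats::cor(X[, S, drop = FALSE], y))[, 1]
  rcc <- if (k < 2) 0 else {
    M <- abs(stats::cor(X[, S, drop = FALSE]))
    (sum(M) - k) / (k * (k - 1))
  }
  k * mean(rcy) / sqrt(k + k * (k - 1) * rcc)
}

# Write a small AIRR rearrangement TSV and return its path.
write_airr_fixture <- function(rows, dir = NULL, name = "sample.tsv") {
  if (is.null(dir)) {
    dir <- tempfile("airr")
    dir.create(dir)
  }
  path <- file.path(dir, name)
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

# A random selector output over G features, for property tests.
random_selector_output <- function(G, type, seed) {
  set.seed(seed)
  switch(type,
    subset = selector_output("s", "subset", G,
                             selected = sort(sample.int(G, sample.int(G, 1)))),
    ordered_subset = selector_output("o", "ordered_subset", G,
                                     selected = sample.int(G, sample.int(G, 1))),
    ranking = {
      r <- sample.int(G)
      selector_output("r", "ranking", G, selected = order(r)[1:3], ranks = r)
    })
}
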
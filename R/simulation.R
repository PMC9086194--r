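#' Registry of benchmark simulation scenarios
#'
#' Returns the eight named scenarios used throughout the simulation study.
#' Each scenario crosses sample size (50, 100), number of features
#' (600, 1200) and outcome prevalence (0.5, 0.25).  The prevalence is
#' controlled by the logistic coefficients on the three causal base
#' variables: `(-9, 6, 3)` for the 0.5 family and `(-14, 12, -6)` for the
#' 0.25 family, with intercept 0 in both.  Every scenario has six
#' correlated groups of size 10 (three causal, three non-causal decoys),
#' so 30 causal features out of G.
#'
#' @return A named list of `repsel_scenario` objects.
#' @seealso [simulate_dataset()], [make_replicate_pairs()]
#' @export
#' @examples
#' names(scenario_registry())
#' scenario_registry()[["n100_G600_eta0.5"]]
scenario_registry <- function() {
  grid <- expand.grid(n = c(50L, 100L), G = c(600L, 1200L),
                      eta = c(0.5, 0.25), KEEP.OUT.ATTRS = FALSE)
  sc <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n[i]; G <- grid$G[i]; eta <- grid$eta[i]
    beta <- if (eta == 0.5) c(0, -9, 6, 3) else c(0, -14, 12, -6)
    simulation_scenario(
      label = sprintf("n%d_G%d_eta%s", n, G, format(eta)),
      n = n, G = G, eta = eta, beta = beta
    )
  })
  names(sc) <- vapply(sc, `[[`, character(1), "label")
  ## fixed presentation order: eta 0.5 family first, within family by (n, G)
  ord <- c("n50_G600_eta0.5", "n50_G1200_eta0.5", "n100_G600_eta0.5",
           "n100_G1200_eta0.5", "n50_G600_eta0.25", "n50_G1200_eta0.25",
           "n100_G600_eta0.25", "n100_G1200_eta0.25")
  sc[ord]
}

#' Construct a simulation scenario
#'
#' A scenario fully determines one synthetic dataset draw (given a seed):
#' a binary outcome from a logistic model on three latent base variables,
#' six groups of correlated observed features, and uniform noise features.
#'
#' @param label Character scenario label.
#' @param n Sample size.
#' @param G Total number of observed features; must be at least the number
#'   of correlated features `sum(group_sizes)`.
#' @param eta Target marginal prevalence `P(Y = 1)` (descriptive; the
#'   realised prevalence is driven by `beta`).
#' @param beta Numeric length-4 vector `(beta0, beta1, beta2, beta3)` of
#'   logistic coefficients on the first three base variables.
#' @param group_sizes Integer vector of the six correlated-group sizes
#'   (default 10 each; groups 1-3 causal, 4-6 non-causal decoys).
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   base variable when generating correlated features (default 0.3).
#' @return A `repsel_scenario` object (a validated list).
#' @export
simulation_scenario <- function(label, n, G, eta, beta,
                                group_sizes = rep(10L, 6L), noise_sd = 0.3) {
  stopifnot(is.character(label), length(label) == 1L,
            n >= 2, G >= 1, length(beta) == 4L, is.numeric(beta),
            length(group_sizes) == 6L, noise_sd > 0)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 2))
    stop("each correlated group must have size >= 2 (the noise-scale ",
         "formula divides by group size minus one)", call. = FALSE)
  if (sum(group_sizes) > G)
    stop("sum of group sizes exceeds G", call. = FALSE)
  structure(list(label = label, n = as.integer(n), G = as.integer(G),
                 eta = eta, beta = as.numeric(beta),
                 group_sizes = group_sizes, noise_sd = noise_sd),
            class = "repsel_scenario")
}

#' @export
print.repsel_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario '%s'\n", x$label))
  cat(sprintf("  n = %d, G = %d, target P(Y=1) = %s\n", x$n, x$G,
              format(x$eta)))
  cat(sprintf("  beta = (%s); causal features = %d of %d\n",
              paste(format(x$beta), collapse = ", "),
              sum(x$group_sizes[1:3]), x$G))
  invisible(x)
}

#' Simulate one dataset from a scenario
#'
#' Draws six latent base variables `x_1..x_6 ~ iid Uniform(0,1)` per
#' subject.  Group `i` contributes `g_i` observed features
#' `v_i(j) = x_i + (0.01 + 0.5 (j-1)/(g_i-1)) * N(0, sd = noise_sd)`,
#' with fresh noise per subject and feature, so the correlation between
#' `x_i` and `v_i(j)` decays as `j` grows.  The remaining `G - sum(g_i)`
#' features are iid Uniform(0,1) noise.  The outcome is Bernoulli with
#' `logit P(Y=1) = beta0 + beta1 x1 + beta2 x2 + beta3 x3`.  Only the
#' `v` and `w` features enter the returned design; the latent bases are
#' kept separately for diagnostics.
#'
#' Columns are ordered `v1(1..g1), ..., v6(1..g6), w1, ...`; features in
#' groups 1-3 are flagged causal.
#'
#' @param sc A `repsel_scenario`.
#' @param seed Integer seed for the draw.
#' @return A `repsel_simdata` list with elements `X` (n x G matrix),
#'   `y` (0/1 integer vector), `causal` (logical length G), `group`
#'   (integer 1-6 for correlated features, NA for uniform noise),
#'   `bases` (n x 6 latent matrix) and `scenario`.
#' @export
simulate_dataset <- function(sc, seed) {
  stopifnot(inherits(sc, "repsel_scenario"))
  set.seed(as.integer(seed))
  n <- sc$n; G <- sc$G; g <- sc$group_sizes
  bases <- matrix(stats::runif(n * 6L), n, 6L,
                  dimnames = list(NULL, paste0("x", 1:6)))
  ncorr <- sum(g)
  V <- matrix(NA_real_, n, ncorr)
  grp <- integer(ncorr)
  vnames <- character(ncorr)
  col <- 0L
  for (i in 1:6) {
    for (j in seq_len(g[i])) {
      col <- col + 1L
      scale_j <- 0.01 + 0.5 * (j - 1) / (g[i] - 1)
      V[, col] <- bases[, i] + scale_j * stats::rnorm(n, 0, sc$noise_sd)
      grp[col] <- i
      vnames[col] <- sprintf("v%d_%d", i, j)
    }
  }
  nw <- G - ncorr
  W <- matrix(stats::runif(n * nw), n, nw)
  X <- cbind(V, W)
  colnames(X) <- c(vnames, if (nw > 0) paste0("w", seq_len(nw)))
  lp <- sc$beta[1] + bases[, 1:3, drop = FALSE] %*% sc$beta[2:4]
  y <- stats::rbinom(n, 1L, stats::plogis(drop(lp)))
  causal <- c(grp %in% 1:3, rep(FALSE, nw))
  structure(list(X = X, y = y, causal = causal,
                 group = c(grp, rep(NA_integer_, nw)),
                 bases = bases, scenario = sc, seed = as.integer(seed)),
            class = "repsel_simdata")
}

#' Simulate paired train/test replicates
#'
#' Each replicate pair consists of two independent datasets from the same
#' scenario: the first intended for feature selection and classifier
#' training, the second for stability assessment and prediction
#' evaluation.  Per-dataset seeds are derived deterministically from the
#' master seed, so the same master seed reproduces the pair list exactly.
#'
#' @param sc A `repsel_scenario`.
#' @param n_pairs Number of replicate pairs.
#' @param seed Master seed.
#' @return A list of length `n_pairs`; each element is a list with
#'   components `train` and `test` (both `repsel_simdata`).
#' @export
make_replicate_pairs <- function(sc, n_pairs, seed) {
  stopifnot(n_pairs >= 1)
  seeds <- derive_seeds(seed, 2L * n_pairs)
  lapply(seq_len(n_pairs), function(k) {
    list(train = simulate_dataset(sc, seeds[2L * k - 1L]),
         test  = simulate_dataset(sc, seeds[2L * k]))
  })
}

## Derive m child seeds from one master seed, reproducibly and without
## disturbing the caller's RNG stream more than once.
derive_seeds <- function(seed, m) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, m)
}
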
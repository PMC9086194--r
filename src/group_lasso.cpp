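#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Group-lasso penalized logistic regression along a decreasing lambda
// grid, by blockwise majorize-minimize coordinate descent with warm
// starts and an active-set strategy.  The objective at each lambda is
//   Q(b0, beta) = -loglik + lambda * sum_b s_b * ||beta_b||_2 ,
// with the intercept unpenalized.  Each block update majorizes the
// negative log-likelihood by a quadratic with curvature
// L_b = eigmax(X_b' X_b) / 4 (the logistic Hessian bound 1/4), giving
// the group soft-threshold step
//   beta_b <- (1 - lambda s_b / (L_b ||v||))_+ v,  v = beta_b + X_b' r / L_b,
// where r = y - p is the current residual.  Every step decreases Q.
//
// Per lambda: sweep the intercept and currently-active blocks to
// convergence, then do one full Karush-Kuhn-Tucker pass over the
// inactive blocks (a zero block stays optimal iff ||X_b' r|| <=
// lambda s_b); violators join the active set and the cycle repeats.
//
// grp: 0-based block id per column.  Returns coefficients per lambda
// and the number of inner sweeps used.

static double block_curvature(const mat& Xb) {
  if (Xb.n_cols == 1) return dot(Xb.col(0), Xb.col(0)) / 4.0;
  vec ev = eig_sym(symmatu(Xb.t() * Xb));
  return ev.max() / 4.0;
}

// [[Rcpp::export(name = ".gl_logistic_path")]]
Rcpp::List gl_logistic_path(const arma::mat& X,
                            const arma::vec& y,
                            const arma::ivec& grp,
                            const arma::vec& sb,
                            const arma::vec& lambda,
                            const double tol = 1e-5,
                            const int max_sweeps = 1000,
                            const double dev_ratio_max = 0.999,
                            const double fdev = 1e-5) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword B = sb.n_elem;
  const uword nlam = lambda.n_elem;

  std::vector<uvec> cols(B);
  {
    std::vector<std::vector<uword>> tmp(B);
    for (uword j = 0; j < p; ++j) tmp[grp(j)].push_back(j);
    for (uword b = 0; b < B; ++b) cols[b] = conv_to<uvec>::from(tmp[b]);
  }
  vec L(B);
  for (uword b = 0; b < B; ++b) {
    L(b) = block_curvature(X.cols(cols[b]));
    if (L(b) <= 0) L(b) = 1e-12;  // all-zero block: never enters
  }
  const double Lint = n / 4.0;

  vec beta(p, fill::zeros);
  double beta0 = std::log(mean(y) / (1.0 - mean(y)));
  mat beta_path(p, nlam, fill::zeros);
  vec beta0_path(nlam, fill::zeros);
  ivec sweeps(nlam, fill::zeros);

  vec eta = beta0 + X * beta;
  std::vector<bool> active(B, false);

  // null deviance, for the saturation stop
  const double ybar = mean(y);
  const double null_dev =
      -2.0 * accu(y * std::log(ybar) + (1.0 - y) * std::log(1.0 - ybar));

  uword l_stop = nlam;
  double dev_prev = null_dev;
  for (uword l = 0; l < nlam; ++l) {
    const double lam = lambda(l);
    int it = 0;
    bool done = false;
    while (!done && it < max_sweeps) {
      // inner sweeps over intercept + active blocks
      for (; it < max_sweeps; ++it) {
        double max_change = 0.0;
        {
          vec pr = 1.0 / (1.0 + exp(-eta));
          double d0 = accu(y - pr) / Lint;
          beta0 += d0;
          eta += d0;
          max_change = std::fabs(d0);
        }
        for (uword b = 0; b < B; ++b) {
          if (!active[b]) continue;
          const uvec& cb = cols[b];
          vec pr = 1.0 / (1.0 + exp(-eta));
          vec g = X.cols(cb).t() * (y - pr);
          vec old = beta(cb);
          vec v = old + g / L(b);
          double vn = norm(v, 2);
          double thr = lam * sb(b) / L(b);
          vec nw(cb.n_elem, fill::zeros);
          if (vn > thr) nw = (1.0 - thr / vn) * v;
          vec d = nw - old;
          double dn = norm(d, "inf");
          if (dn > 0) {
            beta(cb) = nw;
            eta += X.cols(cb) * d;
            if (dn > max_change) max_change = dn;
          }
          if (norm(nw, 2) == 0.0) active[b] = false;
        }
        double scale = std::max(1.0, norm(beta, "inf"));
        if (max_change < tol * scale) { ++it; break; }
      }
      // full KKT pass over inactive blocks: one gradient for all
      vec pr = 1.0 / (1.0 + exp(-eta));
      vec g = X.t() * (y - pr);
      done = true;
      for (uword b = 0; b < B; ++b) {
        if (active[b]) continue;
        double gn = norm(g(cols[b]), 2);
        if (gn > lam * sb(b) * (1.0 + 1e-10)) {
          active[b] = true;
          done = false;
        }
      }
    }
    if (it >= max_sweeps)
      Rcpp::warning("group lasso did not converge at lambda = %g", lam);
    sweeps(l) = it;
    beta_path.col(l) = beta;
    beta0_path(l) = beta0;

    // freeze the path (constant extension) once the fit is essentially
    // saturated or a lambda step no longer improves the deviance:
    // smaller lambda values only inflate coefficients along the
    // separating direction without changing which blocks are active
    double dev = -2.0 * (accu(y % eta) - accu(log1p(exp(eta))));
    if (1.0 - dev / null_dev > dev_ratio_max ||
        (l > 0 && dev_prev - dev < fdev * null_dev)) {
      l_stop = l + 1;
      break;
    }
    dev_prev = dev;
  }
  for (uword l = l_stop; l < nlam; ++l) {
    beta_path.col(l) = beta;
    beta0_path(l) = beta0;
  }

  return Rcpp::List::create(
      Rcpp::Named("beta0") = beta0_path,
      Rcpp::Named("beta") = beta_path,
      Rcpp::Named("sweeps") = sweeps);
}
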
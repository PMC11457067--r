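// Bayesian multivariate Gaussian sampler for genomic prediction across
// correlated response columns (sites and/or surrogate traits):
//
//   y_ij = mu_j + g_ij + e_ij,  vec(g) ~ N(0, Ta (x) G),
//   e_ij ~ N(0, sigma2_j) on observed cells only.
//
// Full conditionals: flat-prior column intercepts; breeding-value rows
// g_i. (t-vector per genotype) sampled single-site using the conditional
// prior implied by Ginv, so no nt x nt matrix is ever formed; Ta from an
// inverse-Wishart; per-column residual variances from scaled inverse
// chi-square. Missing cells simply drop out of the likelihood — no data
// augmentation is needed to predict g. All randomness comes from R's RNG,
// so set.seed() on the R side makes chains exactly reproducible.

#include <RcppArmadillo.h>
using namespace arma;

static arma::mat rinvwishart(double df, const arma::mat& S) {
  // Ta ~ IW(df, S): draw W ~ Wishart(df, S^{-1}) by Bartlett, return W^{-1}
  const uword t = S.n_rows;
  mat Sinv = inv_sympd(symmatu(0.5 * (S + S.t())));
  mat L = chol(Sinv, "lower");
  mat A(t, t, fill::zeros);
  for (uword i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double) i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  mat W = LA * LA.t();
  return inv_sympd(symmatu(0.5 * (W + W.t())));
}

// [[Rcpp::export]]
Rcpp::List gibbs_mtm_cpp(const arma::mat& Y,        // n x t, NaN = missing
                         const arma::mat& Ginv,
                         int n_iter, int burn_in, int thin,
                         double nu0, const arma::mat& S0,
                         double df_e, double scale_e) {
  const uword n = Y.n_rows, t = Y.n_cols;
  umat obs(n, t);
  vec n_obs(t, fill::zeros);
  for (uword j = 0; j < t; ++j)
    for (uword i = 0; i < n; ++i) {
      obs(i, j) = std::isfinite(Y(i, j)) ? 1u : 0u;
      n_obs(j) += obs(i, j);
    }

  // initial values
  vec mu(t), sigma2(t);
  for (uword j = 0; j < t; ++j) {
    vec col = Y.col(j);
    double s = 0.0, ss = 0.0;
    for (uword i = 0; i < n; ++i) if (obs(i, j)) s += col(i);
    mu(j) = s / n_obs(j);
    for (uword i = 0; i < n; ++i) if (obs(i, j)) ss += std::pow(col(i) - mu(j), 2);
    sigma2(j) = std::max(ss / n_obs(j), 1e-6) * 0.5;
  }
  mat Ta = eye(t, t) * 0.5;
  mat g(n, t, fill::zeros);
  mat Sg = Ginv * g;                       // running Ginv * g

  const int n_keep = (n_iter - burn_in) / thin;
  mat Ta_draws(n_keep, t * t);
  mat s2_draws(n_keep, t), mu_draws(n_keep, t);
  mat g_mean(n, t, fill::zeros);
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // (a) intercepts
    for (uword j = 0; j < t; ++j) {
      double s = 0.0;
      for (uword i = 0; i < n; ++i) if (obs(i, j)) s += Y(i, j) - g(i, j);
      mu(j) = s / n_obs(j) + std::sqrt(sigma2(j) / n_obs(j)) * R::norm_rand();
    }
    // (b) breeding-value rows, single-site given the rest
    mat Tainv = inv_sympd(symmatu(0.5 * (Ta + Ta.t())));
    for (uword i = 0; i < n; ++i) {
      const double gii = Ginv(i, i);
      rowvec cross = Sg.row(i) - gii * g.row(i);
      vec rhs = -(Tainv * cross.t());
      mat P = gii * Tainv;
      for (uword j = 0; j < t; ++j) {
        if (obs(i, j)) {
          P(j, j) += 1.0 / sigma2(j);
          rhs(j) += (Y(i, j) - mu(j)) / sigma2(j);
        }
      }
      mat L = chol(P, "lower");
      vec m = solve(trimatu(L.t()), solve(trimatl(L), rhs));
      vec z(t);
      for (uword j = 0; j < t; ++j) z(j) = R::norm_rand();
      vec gnew = m + solve(trimatu(L.t()), z);
      rowvec delta = gnew.t() - g.row(i);
      g.row(i) = gnew.t();
      Sg += Ginv.col(i) * delta;           // rank-1 refresh of Ginv * g
    }
    // (c) genetic covariance; recomputing Ginv*g here also resets any
    // drift the rank-1 refreshes accumulated during (b)
    Sg = Ginv * g;
    mat SS = g.t() * Sg;
    Ta = rinvwishart(nu0 + (double) n, S0 + SS);
    // (d) residual variances
    for (uword j = 0; j < t; ++j) {
      double ss = 0.0;
      for (uword i = 0; i < n; ++i) if (obs(i, j)) ss += std::pow(Y(i, j) - mu(j) - g(i, j), 2);
      sigma2(j) = (df_e * scale_e + ss) / R::rchisq(df_e + n_obs(j));
    }
    if (!mu.is_finite() || !g.is_finite() || !Ta.is_finite() || !sigma2.is_finite())
      Rcpp::stop("divergent chain at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      Ta_draws.row(keep) = vectorise(Ta).t();
      s2_draws.row(keep) = sigma2.t();
      mu_draws.row(keep) = mu.t();
      g_mean += g;
      ++keep;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }
  g_mean /= (double) keep;

  return Rcpp::List::create(
    Rcpp::Named("g_mean") = g_mean,
    Rcpp::Named("mu_draws") = mu_draws,
    Rcpp::Named("Ta_draws") = Ta_draws,
    Rcpp::Named("sigma2_draws") = s2_draws,
    Rcpp::Named("n_retained") = keep);
}
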
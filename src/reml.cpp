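// Multitrait GBLUP via REML.
//
// Model per record i:  y_i = x_i' beta + g[trait_i, geno_i] + e_i
// with vec(g) ~ N(0, Ta (x) G) (trait-major ordering) and e_i ~ N(0,
// sigma2[trait_i]) independent (diagonal residual covariance across
// traits). Estimation is EM-REML warm-up followed by average-information
// (AI) updates with step-halving back to EM when an update leaves the
// parameter space.
//
// The mixed-model equations are assembled densely; C^{-1} is required in
// full for the trace terms and prediction error variances, so problem
// sizes are expected at the hundreds-of-genotypes scale.

#include <RcppArmadillo.h>
#include <limits>
using namespace arma;

// trait-major effect index
static inline uword eff(uword trait, uword geno, uword q) { return trait * q + geno; }

// [[Rcpp::export]]
Rcpp::List reml_fit_cpp(const arma::vec& y,
                        const arma::uvec& trait,
                        const arma::uvec& geno,
                        const arma::mat& X,
                        const arma::mat& G,
                        const arma::mat& Ginv,
                        double logdetG,
                        arma::mat Ta,
                        arma::vec sigma2,
                        int max_iter,
                        double tol,
                        int n_em,
                        bool use_ai) {
  const uword N = y.n_elem, p = X.n_cols, q = Ginv.n_rows, t = Ta.n_rows;
  const uword dim = p + q * t;

  vec n_t(t, fill::zeros);
  for (uword i = 0; i < N; ++i) n_t(trait(i)) += 1.0;

  mat C(dim, dim), Cinv;
  vec rhs(dim), sol(dim), ehat(N), loglik_trace;
  std::vector<double> ll_hist;
  bool converged = false;
  int iter = 0, ai_steps = 0;

  // parameter vector layout: Ta upper triangle (col-major c<=d), then sigma2
  const uword nTa = t * (t + 1) / 2, npar = nTa + t;
  auto pack = [&](const mat& T, const vec& s) {
    vec th(npar); uword k = 0;
    for (uword d = 0; d < t; ++d) for (uword c = 0; c <= d; ++c) th(k++) = T(c, d);
    for (uword j = 0; j < t; ++j) th(k++) = s(j);
    return th;
  };
  auto unpack = [&](const vec& th, mat& T, vec& s) {
    uword k = 0;
    for (uword d = 0; d < t; ++d) for (uword c = 0; c <= d; ++c) { T(c, d) = th(k); T(d, c) = th(k); ++k; }
    for (uword j = 0; j < t; ++j) s(j) = th(k++);
  };

  mat S(t, t);          // S(c,d) = tr(Ginv Cgg_cd)
  mat gmat(q, t);       // BLUPs by trait
  vec beta(p);
  vec tr_rec(t);        // per-trait sum of w_row' Cinv w_row
  double logdetC = 0.0, yPy = 0.0;

  auto assemble_solve = [&]() {
    vec w(N);
    for (uword i = 0; i < N; ++i) w(i) = 1.0 / sigma2(trait(i));
    C.zeros(); rhs.zeros();
    // X'WX, X'Wy
    for (uword i = 0; i < N; ++i) {
      const double wi = w(i);
      for (uword a = 0; a < p; ++a) {
        const double xa = X(i, a);
        if (xa == 0.0) continue;
        rhs(a) += wi * xa * y(i);
        for (uword b = a; b < p; ++b) C(a, b) += wi * xa * X(i, b);
      }
    }
    for (uword a = 0; a < p; ++a)
      for (uword b = a + 1; b < p; ++b) C(b, a) = C(a, b);
    // X'WZ, Z'WZ (diagonal), Z'Wy
    for (uword i = 0; i < N; ++i) {
      const double wi = w(i);
      const uword e = p + eff(trait(i), geno(i), q);
      for (uword a = 0; a < p; ++a) {
        const double xa = X(i, a);
        if (xa != 0.0) { C(a, e) += wi * xa; C(e, a) += wi * xa; }
      }
      C(e, e) += wi;
      rhs(e) += wi * y(i);
    }
    // + Tainv (x) Ginv
    mat Tainv = inv_sympd(Ta);
    for (uword c = 0; c < t; ++c)
      for (uword d = 0; d < t; ++d) {
        const double f = Tainv(c, d);
        if (f == 0.0) continue;
        C.submat(p + c * q, p + d * q, p + c * q + q - 1, p + d * q + q - 1) += f * Ginv;
      }
    logdetC = log_det_sympd(C);
    Cinv = inv_sympd(C);
    sol = Cinv * rhs;
    beta = sol.head(p);
    for (uword c = 0; c < t; ++c) gmat.col(c) = sol.subvec(p + c * q, p + c * q + q - 1);
    // residuals, y'Py
    yPy = 0.0;
    for (uword i = 0; i < N; ++i) {
      double fit = dot(X.row(i), beta) + gmat(geno(i), trait(i));
      ehat(i) = y(i) - fit;
      yPy += w(i) * y(i) * ehat(i);
    }
    // S(c,d) and per-trait trace of W Cinv W'
    for (uword c = 0; c < t; ++c)
      for (uword d = c; d < t; ++d) {
        const mat Ccd = Cinv.submat(p + c * q, p + d * q, p + c * q + q - 1, p + d * q + q - 1);
        double s = accu(Ginv % Ccd.t());
        S(c, d) = s; S(d, c) = s;
      }
    tr_rec.zeros();
    for (uword i = 0; i < N; ++i) {
      const uword e = p + eff(trait(i), geno(i), q);
      double quad = Cinv(e, e);
      for (uword a = 0; a < p; ++a) {
        const double xa = X(i, a);
        if (xa == 0.0) continue;
        quad += 2.0 * xa * Cinv(a, e);
        for (uword b = 0; b < p; ++b) quad += xa * X(i, b) * Cinv(a, b);
      }
      tr_rec(trait(i)) += quad;
    }
    // REML log-likelihood (up to a constant)
    double ll = 0.0;
    for (uword j = 0; j < t; ++j) ll += n_t(j) * std::log(sigma2(j));
    double sign, ldTa; log_det(ldTa, sign, Ta);
    ll += q * ldTa + t * logdetG + logdetC + yPy;
    return -0.5 * ll;
  };

  auto em_update = [&](mat& Tnew, vec& snew) {
    mat GinvU = Ginv * gmat;               // q x t
    for (uword c = 0; c < t; ++c)
      for (uword d = c; d < t; ++d) {
        double v = (dot(gmat.col(c), GinvU.col(d)) + S(c, d)) / (double) q;
        Tnew(c, d) = v; Tnew(d, c) = v;
      }
    vec ss(t, fill::zeros);
    for (uword i = 0; i < N; ++i) ss(trait(i)) += ehat(i) * ehat(i);
    for (uword j = 0; j < t; ++j) snew(j) = (ss(j) + tr_rec(j)) / n_t(j);
  };

  auto ai_update = [&](mat& Tnew, vec& snew) -> bool {
    mat Tainv = inv_sympd(Ta);
    vec r(N);
    for (uword i = 0; i < N; ++i) r(i) = ehat(i) / sigma2(trait(i));
    mat U(q, t, fill::zeros);              // Z'r by trait
    for (uword i = 0; i < N; ++i) U(geno(i), trait(i)) += r(i);
    mat GU = G * U;
    mat M = Tainv * S * Tainv;

    vec score(npar), theta = pack(Ta, sigma2);
    uword k = 0;
    for (uword d = 0; d < t; ++d)
      for (uword c = 0; c <= d; ++c) {
        double mult = (c == d) ? 1.0 : 2.0;
        double quad = mult * dot(U.col(c), GU.col(d));
        double trc = mult * ((double) q * Tainv(c, d) - M(c, d));
        score(k++) = -0.5 * (trc - quad);
      }
    for (uword j = 0; j < t; ++j) {
      double quad = 0.0, rr = 0.0;
      for (uword i = 0; i < N; ++i) if (trait(i) == j) { quad += r(i) * r(i); }
      rr = n_t(j) / sigma2(j) - tr_rec(j) / (sigma2(j) * sigma2(j));
      score(k++) = -0.5 * (rr - quad);
    }

    // derivative-times-residual vectors and their P-projections
    mat Tvec(N, npar, fill::zeros);
    k = 0;
    for (uword d = 0; d < t; ++d)
      for (uword c = 0; c <= d; ++c) {
        for (uword i = 0; i < N; ++i) {
          const uword ti = trait(i);
          if (c == d) { if (ti == c) Tvec(i, k) = GU(geno(i), c); }
          else {
            if (ti == c) Tvec(i, k) = GU(geno(i), d);
            else if (ti == d) Tvec(i, k) = GU(geno(i), c);
          }
        }
        ++k;
      }
    for (uword j = 0; j < t; ++j) {
      for (uword i = 0; i < N; ++i) if (trait(i) == j) Tvec(i, k) = r(i);
      ++k;
    }
    mat Pt(N, npar);
    for (uword m = 0; m < npar; ++m) {
      vec v = Tvec.col(m);
      vec wv(dim, fill::zeros);
      for (uword i = 0; i < N; ++i) {
        const double wvi = v(i) / sigma2(trait(i));
        if (wvi == 0.0) continue;
        for (uword a = 0; a < p; ++a) wv(a) += wvi * X(i, a);
        wv(p + eff(trait(i), geno(i), q)) += wvi;
      }
      vec s2 = Cinv * wv;
      for (uword i = 0; i < N; ++i) {
        double fit = dot(X.row(i), s2.head(p)) + s2(p + eff(trait(i), geno(i), q));
        Pt(i, m) = (v(i) - fit) / sigma2(trait(i));
      }
    }
    mat AI = 0.5 * (Tvec.t() * Pt);
    AI = 0.5 * (AI + AI.t());
    // near-collinear derivative directions (e.g. two almost-identical
    // traits) make AI singular; damp the solve Levenberg-Marquardt style
    vec delta;
    bool solved = false;
    double base = std::max(trace(AI) / (double) npar, 1e-12);
    for (double lam : {0.0, 1e-8, 1e-4, 1e-2}) {
      mat AId = AI + lam * base * eye(npar, npar);
      if (solve(delta, AId, score, solve_opts::likely_sympd + solve_opts::no_approx)) {
        solved = true;
        break;
      }
    }
    if (!solved) return false;

    double step = 1.0;
    for (int h = 0; h < 12; ++h, step *= 0.5) {
      vec thn = theta + step * delta;
      mat Tt(t, t); vec st(t);
      unpack(thn, Tt, st);
      if (st.min() <= 0.0) continue;
      mat L;
      if (!chol(L, Tt)) continue;
      Tnew = Tt; snew = st;
      return true;
    }
    return false;
  };

  double ll_prev = -std::numeric_limits<double>::infinity();
  for (iter = 1; iter <= max_iter; ++iter) {
    double ll = assemble_solve();
    ll_hist.push_back(ll);
    mat Tnew(t, t); vec snew(t);
    bool ai_ok = false;
    if (use_ai && iter > n_em) ai_ok = ai_update(Tnew, snew);
    if (ai_ok) ++ai_steps; else em_update(Tnew, snew);
    // relative parameter change, so large-variance traits are not held to
    // an absolute yardstick
    double scale_ref = std::max(1.0, std::max(abs(Ta).max(), sigma2.max()));
    double dmax = std::max(abs(Tnew - Ta).max(), abs(snew - sigma2).max()) / scale_ref;
    Ta = Tnew; sigma2 = snew;
    // a flat restricted likelihood means the remaining parameter drift is
    // along a ridge the data cannot resolve: accept convergence
    bool ll_flat = (iter > n_em + 2) && std::abs(ll - ll_prev) < 1e-9 * (1.0 + std::abs(ll));
    ll_prev = ll;
    if (dmax < tol || ll_flat) { converged = true; break; }
  }
  // final solve at converged parameters
  double ll = assemble_solve();
  ll_hist.push_back(ll);

  // PEV and per-trait Cgg blocks
  mat pev(q, t);
  Rcpp::List Cgg(t);
  for (uword c = 0; c < t; ++c) {
    mat blk = Cinv.submat(p + c * q, p + c * q, p + c * q + q - 1, p + c * q + q - 1);
    pev.col(c) = blk.diag();
    Cgg[c] = blk;
  }

  return Rcpp::List::create(
    Rcpp::Named("Ta") = Ta,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("g") = gmat,
    Rcpp::Named("pev") = pev,
    Rcpp::Named("Cgg") = Cgg,
    Rcpp::Named("loglik") = vec(ll_hist),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("ai_steps") = ai_steps,
    Rcpp::Named("iterations") = iter);
}
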
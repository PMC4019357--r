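// Gibbs sampler with Metropolis phi update for the spatial regression
//   y = X beta + w + eps,  w ~ GP(0, sigma2 * R),  R_ij = exp(-phi d_ij),
//   eps ~ N(0, tau2 I)
// Conjugate updates: beta (flat prior, normal), sigma2 and tau2
// (inverse-gamma), w (multivariate normal); phi gets a log-scale
// random-walk Metropolis step under a uniform prior on [phi_lo, phi_hi],
// tuned during burn-in. Uses R's RNG throughout so set.seed() governs the
// whole chain.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double logdet_from_chol(const arma::mat& U) {
  return 2.0 * arma::accu(arma::log(U.diag()));
}

// [[Rcpp::export]]
List splm_gibbs(const arma::vec& y, const arma::mat& X, const arma::mat& D,
                double phi_lo, double phi_hi,
                double ig_a_sigma, double ig_b_sigma,
                double ig_a_tau, double ig_b_tau,
                int n_iter, int burn_in, int thin,
                double phi_init, double sigma2_init, double tau2_init,
                double step_init) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const double jitter = 1e-10;

  arma::mat XtX = X.t() * X;
  arma::mat XtXinv = arma::inv_sympd(XtX);
  arma::mat U_xtxinv = arma::chol(XtXinv);   // upper: U'U = XtXinv

  double phi = phi_init, sigma2 = sigma2_init, tau2 = tau2_init;
  double step = step_init;

  arma::mat R = arma::exp(-phi * D);
  R.diag() += jitter;
  arma::mat cholR = arma::chol(R);
  arma::mat Rinv = arma::inv_sympd(R);
  double logdetR = logdet_from_chol(cholR);

  // start beta at OLS, w at zero
  arma::vec beta = XtXinv * (X.t() * y);
  arma::vec w(n, arma::fill::zeros);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::mat beta_s(n_keep, p), w_s(n_keep, n);
  arma::vec sigma2_s(n_keep), tau2_s(n_keep), phi_s(n_keep);

  int keep = 0, acc = 0, acc_win = 0, win = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- w | . ---
    arma::mat A = Rinv / sigma2;
    A.diag() += 1.0 / tau2;
    arma::mat cholA = arma::chol(A);
    arma::vec b = (y - X * beta) / tau2;
    arma::vec m = arma::solve(arma::trimatu(cholA),
                              arma::solve(arma::trimatl(cholA.t()), b));
    arma::vec z(n);
    for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
    w = m + arma::solve(arma::trimatu(cholA), z);

    // --- beta | . (flat prior) ---
    arma::vec bmean = XtXinv * (X.t() * (y - w));
    arma::vec zp(p);
    for (int j = 0; j < p; ++j) zp(j) = R::norm_rand();
    beta = bmean + std::sqrt(tau2) * (U_xtxinv.t() * zp);

    // --- tau2 | . ---
    arma::vec resid = y - X * beta - w;
    double rate_t = ig_b_tau + 0.5 * arma::dot(resid, resid);
    tau2 = 1.0 / R::rgamma(ig_a_tau + 0.5 * n, 1.0 / rate_t);

    // --- sigma2 | . ---
    double quad = arma::as_scalar(w.t() * Rinv * w);
    double rate_s = ig_b_sigma + 0.5 * quad;
    sigma2 = 1.0 / R::rgamma(ig_a_sigma + 0.5 * n, 1.0 / rate_s);

    // --- phi | . : log-RW Metropolis, uniform prior on [phi_lo, phi_hi] ---
    double phi_prop = phi * std::exp(step * R::norm_rand());
    if (phi_prop >= phi_lo && phi_prop <= phi_hi) {
      arma::mat Rp = arma::exp(-phi_prop * D);
      Rp.diag() += jitter;
      arma::mat cholRp;
      bool ok = arma::chol(cholRp, Rp);
      if (ok) {
        double logdetRp = logdet_from_chol(cholRp);
        arma::vec v = arma::solve(arma::trimatl(cholRp.t()), w);
        double quad_p = arma::dot(v, v);
        double ll_cur = -0.5 * logdetR - 0.5 * quad / sigma2;
        double ll_prop = -0.5 * logdetRp - 0.5 * quad_p / sigma2;
        double log_alpha = ll_prop - ll_cur + std::log(phi_prop) - std::log(phi);
        if (std::log(R::unif_rand()) < log_alpha) {
          phi = phi_prop;
          R = Rp; cholR = cholRp; logdetR = logdetRp;
          Rinv = arma::inv_sympd(R);
          ++acc; ++acc_win;
        }
      }
    }

    // tune the proposal toward 25-45% acceptance during burn-in
    ++win;
    if (it < burn_in && win == 100) {
      double rate = acc_win / 100.0;
      if (rate > 0.45) step *= 1.25;
      else if (rate < 0.25) step /= 1.25;
      acc_win = 0; win = 0;
    }
    if (it >= burn_in) { win = 0; }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      beta_s.row(keep) = beta.t();
      w_s.row(keep) = w.t();
      sigma2_s(keep) = sigma2;
      tau2_s(keep) = tau2;
      phi_s(keep) = phi;
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_s.rows(0, keep - 1),
    _["w"] = w_s.rows(0, keep - 1),
    _["sigma2"] = sigma2_s.subvec(0, keep - 1),
    _["tau2"] = tau2_s.subvec(0, keep - 1),
    _["phi"] = phi_s.subvec(0, keep - 1),
    _["acceptance_rate"] = static_cast<double>(acc) / n_iter,
    _["final_step"] = step
  );
}
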
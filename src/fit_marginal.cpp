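// Marginal-likelihood fitting of the per-CpG latent component-mixture model.
//
// Per CpG j the bulk value follows the marginal Gaussian
//   x_i ~ N( sum_h W_ih mu_h + c_i' delta,  v_i ),
//   v_i = sum_h W_ih^2 sigma2_h + tau2,
// i.e. the variance is linear in theta = (sigma2_1..k, tau2) with design
// u_i = (W_i1^2 .. W_ik^2, 1). The likelihood is maximized by alternating
//   (1) exact generalized least squares for (mu, delta) given v, and
//   (2) a Fisher-scoring step for theta -- the weighted (1/v^2) least
//       squares of the squared residuals on u -- projected onto the
//       feasible region theta >= var_floor, with step-halving backtracking
//       so the objective never decreases.
// The per-iteration log-likelihood trace is therefore non-decreasing by
// construction, and convergence is declared on its relative change.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double loglik_of(const vec& r, const vec& v, double cst) {
  return -0.5 * (accu(log(v)) + accu(square(r) / v)) - cst;
}

// [[Rcpp::export(name = ".fit_marginal_cpp")]]
Rcpp::List fit_marginal_cpp(const arma::mat& X, const arma::mat& W,
                            const arma::mat& C, const arma::mat& mu0,
                            const arma::mat& sigma20, const arma::vec& tau20,
                            const arma::mat& delta0, double tol, int max_iter,
                            double var_floor, bool keep_trace) {
  const uword n = X.n_rows, m = X.n_cols, k = W.n_cols;
  const uword p = C.n_cols;
  const mat D = join_horiz(W, C);          // mean design, n x (k+p)
  mat U = join_horiz(square(W), ones<vec>(n));  // variance design, n x (k+1)
  const uword q = k + 1;

  mat mu = mu0, sigma2 = sigma20, delta = delta0;
  vec tau2 = tau20;
  vec loglik(m), n_iter(m);
  uvec converged(m, fill::zeros);
  const double cst = 0.5 * double(n) * std::log(2.0 * M_PI);
  Rcpp::List trace(keep_trace ? m : 0);

  for (uword j = 0; j < m; ++j) {
    const vec x = X.col(j);
    vec theta(q);
    theta.head(k) = sigma2.row(j).t();
    theta(q - 1) = tau2(j);
    theta = clamp(theta, var_floor, datum::inf);
    vec beta(k + p);
    beta.head(k) = mu.row(j).t();
    if (p > 0) beta.tail(p) = delta.row(j).t();

    double ll_old = -datum::inf, ll = 0.0;
    std::vector<double> tr;
    int it = 0;
    bool conv = false;
    for (it = 1; it <= max_iter; ++it) {
      vec v = U * theta;
      // GLS for the mean given the variances (exact maximizer)
      mat Dw = D.each_col() / sqrt(v);
      vec xw = x / sqrt(v);
      beta = solve(Dw.t() * Dw, Dw.t() * xw, solve_opts::likely_sympd);
      vec r = x - D * beta;
      ll = loglik_of(r, v, cst);
      if (keep_trace) tr.push_back(ll);
      if (it > 1 && std::abs(ll - ll_old) <= tol * (std::abs(ll_old) + 1.0)) {
        conv = true;
        break;
      }
      ll_old = ll;
      if (it == max_iter) break;

      // Fisher-scoring proposal for the variance parameters
      vec r2 = square(r);
      vec wt = 1.0 / square(v);
      mat Uw = U.each_col() % sqrt(wt);
      vec theta_prop;
      bool ok = solve(theta_prop, Uw.t() * Uw, U.t() * (wt % r2));
      if (!ok) theta_prop = theta;
      theta_prop = clamp(theta_prop, var_floor, datum::inf);

      // backtrack so the objective cannot decrease
      double s = 1.0;
      for (int bt = 0; bt < 14; ++bt) {
        vec theta_try = clamp(theta + s * (theta_prop - theta),
                              var_floor, datum::inf);
        vec v_try = U * theta_try;
        if (loglik_of(r, v_try, cst) >= ll - 1e-12 * (std::abs(ll) + 1.0)) {
          theta = theta_try;
          break;
        }
        s *= 0.5;
      }
    }
    mu.row(j) = beta.head(k).t();
    if (p > 0) delta.row(j) = beta.tail(p).t();
    sigma2.row(j) = theta.head(k).t();
    tau2(j) = theta(q - 1);
    loglik(j) = ll;
    n_iter(j) = it;
    converged(j) = conv ? 1 : 0;
    if (keep_trace) trace[j] = Rcpp::NumericVector(tr.begin(), tr.end());
  }

  return Rcpp::List::create(
      Rcpp::Named("mu") = mu, Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("tau2") = tau2, Rcpp::Named("delta") = delta,
      Rcpp::Named("loglik") = loglik, Rcpp::Named("n_iter") = n_iter,
      Rcpp::Named("converged") = converged, Rcpp::Named("trace") = trace);
}
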
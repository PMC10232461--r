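// EM for Gaussian mixtures (1D or 2D, full covariance), used by the
// repeated-fit BIC model-selection protocol. Initial responsibilities are
// supplied from R (seeded random k-means starts) so that the whole
// procedure is reproducible under R's RNG. The univariate path is
// specialized: model selection runs hundreds of thousands of EM fits, and
// the generic matrix path would dominate the run time.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// ---- univariate ----------------------------------------------------------
static Rcpp::List em_gmm_1d(const vec &x, mat resp, double var_floor,
                            int max_iter, double tol) {
  const unsigned n = x.n_elem, k = resp.n_cols;
  vec weights(k), mu(k), s2(k);
  mat logdens(n, k);
  double loglik = -datum::inf;
  int iters = 0, floored = 0;

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    rowvec nk = sum(resp, 0);
    for (unsigned j = 0; j < k; ++j) {
      double nj = std::max(nk(j), 1e-12);
      weights(j) = nj / n;
      double m = dot(resp.col(j), x) / nj;
      mu(j) = m;
      vec d = x - m;
      double v = dot(resp.col(j), square(d)) / nj;
      if (v < var_floor) { v = var_floor; ++floored; }
      s2(j) = v;
      logdens.col(j) = std::log(weights(j)) -
        0.5 * (LOG2PI + std::log(v)) - square(d) / (2.0 * v);
    }
    vec m = max(logdens, 1);
    vec lse = m + log(sum(exp(logdens.each_col() - m), 1));
    double ll = accu(lse);
    resp = exp(logdens.each_col() - lse);
    if (std::abs(ll - loglik) < tol) { loglik = ll; break; }
    loglik = ll;
  }
  cube covs(1, 1, k);
  for (unsigned j = 0; j < k; ++j) covs(0, 0, j) = s2(j);
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights,
    Rcpp::Named("means") = mat(mu),
    Rcpp::Named("covs") = covs,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("iters") = iters,
    Rcpp::Named("n_floored") = floored);
}

// ---- general (d >= 2) ----------------------------------------------------
static double log_mvnorm_const(const mat &chol_lower, unsigned d) {
  double logdet = 0.0;
  for (unsigned i = 0; i < d; ++i) logdet += std::log(chol_lower(i, i));
  return -0.5 * d * LOG2PI - logdet;
}

// [[Rcpp::export]]
Rcpp::List em_gmm_cpp(const arma::mat &X, const arma::mat &resp0,
                      double var_floor, int max_iter, double tol) {
  const unsigned n = X.n_rows, d = X.n_cols, k = resp0.n_cols;
  if (d == 1) return em_gmm_1d(X.col(0), resp0, var_floor, max_iter, tol);

  mat resp = resp0;
  vec weights(k);
  mat means(k, d);
  cube covs(d, d, k);
  mat logdens(n, k);
  double loglik = -datum::inf;
  int iters = 0, floored = 0;

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    rowvec nk = sum(resp, 0);
    for (unsigned j = 0; j < k; ++j) {
      double nj = std::max(nk(j), 1e-12);
      weights(j) = nj / n;
      rowvec mu = (resp.col(j).t() * X) / nj;
      means.row(j) = mu;
      mat D = X.each_row() - mu;
      mat C = (D.each_col() % resp.col(j)).t() * D / nj;
      // variance floor: keep every eigenvalue at or above var_floor
      vec eigval; mat eigvec;
      eig_sym(eigval, eigvec, C);
      bool fl = false;
      for (unsigned e = 0; e < d; ++e)
        if (eigval(e) < var_floor) { eigval(e) = var_floor; fl = true; }
      if (fl) { ++floored; C = eigvec * diagmat(eigval) * eigvec.t(); }
      covs.slice(j) = C;
      mat L = chol(C, "lower");
      double cst = log_mvnorm_const(L, d) + std::log(weights(j));
      mat z = solve(trimatl(L), D.t());
      logdens.col(j) = cst - 0.5 * sum(square(z), 0).t();
    }
    vec m = max(logdens, 1);
    vec lse = m + log(sum(exp(logdens.each_col() - m), 1));
    double ll = accu(lse);
    resp = exp(logdens.each_col() - lse);
    if (std::abs(ll - loglik) < tol) { loglik = ll; break; }
    loglik = ll;
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights,
    Rcpp::Named("means") = means,
    Rcpp::Named("covs") = covs,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("iters") = iters,
    Rcpp::Named("n_floored") = floored);
}
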
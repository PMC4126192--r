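#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the weighted L1 problem
//   min_theta  sum_i v_i (y_i - x_i' theta)^2 + lambda * sum_j pf_j |theta_j|
// using covariance updating: with G = X' diag(v) X and q = X' (v * y),
// the soft-threshold argument for coordinate j is
//   rho_j = q_j - (G theta)_j + G_jj theta_j
// and G theta is maintained incrementally, so a full sweep costs O(p^2)
// regardless of n. Uncentered 0/1 genotype columns are heavily mutually
// correlated, which makes the residual-updating scheme need thousands of
// sweeps; the covariance scheme keeps that affordable.
// pf_j = +Inf pins theta_j at zero (adaptive-lasso convention for a zero
// OLS coefficient). Convergence: max absolute coefficient change < tol.
// Deterministic cycling order 1..p.

static void gram_build(const NumericMatrix& X, const NumericVector& y,
                       const NumericVector& v, std::vector<double>& G,
                       std::vector<double>& q) {
  const int n = X.nrow(), p = X.ncol();
  G.assign((size_t)p * p, 0.0);
  q.assign(p, 0.0);
  for (int j = 0; j < p; ++j) {
    double qj = 0.0;
    for (int i = 0; i < n; ++i) qj += v[i] * X(i, j) * y[i];
    q[j] = qj;
    for (int k = j; k < p; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[i] * X(i, j) * X(i, k);
      G[(size_t)j * p + k] = s;
      G[(size_t)k * p + j] = s;
    }
  }
}

static void cd_gram(const std::vector<double>& G, const std::vector<double>& q,
                    const NumericVector& pf, double lambda, int p,
                    std::vector<double>& th, std::vector<double>& gth,
                    double tol, int max_pass) {
  for (int pass = 0; pass < max_pass; ++pass) {
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      const double zj = G[(size_t)j * p + j];
      if (zj <= 0.0 || !R_finite(pf[j])) {
        if (th[j] != 0.0) {
          const double del = -th[j];
          const double* Gj = &G[(size_t)j * p];
          for (int k = 0; k < p; ++k) gth[k] += Gj[k] * del;
          th[j] = 0.0;
        }
        continue;
      }
      const double rho = q[j] - gth[j] + zj * th[j];
      const double thr = 0.5 * lambda * pf[j];
      double newth;
      if (rho > thr)       newth = (rho - thr) / zj;
      else if (rho < -thr) newth = (rho + thr) / zj;
      else                 newth = 0.0;
      const double del = newth - th[j];
      if (del != 0.0) {
        const double* Gj = &G[(size_t)j * p];
        for (int k = 0; k < p; ++k) gth[k] += Gj[k] * del;
        th[j] = newth;
        const double ad = std::fabs(del);
        if (ad > maxdel) maxdel = ad;
      }
    }
    if (maxdel < tol) break;
  }
}

// [[Rcpp::export]]
NumericVector cd_solve(const NumericMatrix& X, const NumericVector& y,
                       const NumericVector& v, const NumericVector& pf,
                       double lambda, const NumericVector& theta_init,
                       double tol, int max_pass) {
  const int p = X.ncol();
  std::vector<double> G, q, th(theta_init.begin(), theta_init.end());
  gram_build(X, y, v, G, q);
  std::vector<double> gth(p, 0.0);
  for (int j = 0; j < p; ++j)
    if (th[j] != 0.0)
      for (int k = 0; k < p; ++k) gth[k] += G[(size_t)j * p + k] * th[j];
  cd_gram(G, q, pf, lambda, p, th, gth, tol, max_pass);
  return NumericVector(th.begin(), th.end());
}

// Warm-started path over a descending lambda grid at fixed observation
// weights; returns a p x nlambda coefficient matrix.
// [[Rcpp::export]]
NumericMatrix cd_path(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& v, const NumericVector& pf,
                      const NumericVector& lambdas, double tol,
                      int max_pass) {
  const int p = X.ncol(), L = lambdas.size();
  NumericMatrix out(p, L);
  std::vector<double> G, q;
  gram_build(X, y, v, G, q);
  std::vector<double> th(p, 0.0), gth(p, 0.0);
  for (int l = 0; l < L; ++l) {
    cd_gram(G, q, pf, lambdas[l], p, th, gth, tol, max_pass);
    for (int j = 0; j < p; ++j) out(j, l) = th[j];
  }
  return out;
}
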
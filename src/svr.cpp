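#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequential-minimal-optimization solver for epsilon-insensitive support
// vector regression on a precomputed kernel matrix (LIBSVM-style dual).
//
// Variables a_t, t = 0..2n-1: t < n are alpha, t >= n are alpha-star, with
// signs s_t = +1 / -1.  Objective: 1/2 sum s_t s_u a_t a_u K + sum a_t
// (eps - s_t y_t), subject to sum s_t a_t = 0 and 0 <= a_t <= C.
// The regression coefficients are beta_i = alpha_i - alphastar_i and the
// prediction is f(x) = sum_i beta_i K(x_i, x) + b.
//
// [[Rcpp::export(name = ".svr_smo_cpp")]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol, int max_iter) {
  const int n = y.size();
  const int N = 2 * n;
  std::vector<double> a(N, 0.0), G(N);
  auto sgn = [n](int t) { return t < n ? 1.0 : -1.0; };
  auto idx = [n](int t) { return t < n ? t : t - n; };
  for (int t = 0; t < N; ++t) G[t] = eps - sgn(t) * y[idx(t)];

  int iter = 0;
  double m = 0.0, M = 0.0;
  for (; iter < max_iter; ++iter) {
    // working-set selection (maximal violating pair)
    int i = -1, j = -1;
    m = -1e30; M = 1e30;
    for (int t = 0; t < N; ++t) {
      double s = sgn(t);
      bool up = (s > 0 && a[t] < C) || (s < 0 && a[t] > 0);
      bool lo = (s < 0 && a[t] < C) || (s > 0 && a[t] > 0);
      double v = -s * G[t];
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    int ii = idx(i), jj = idx(j);
    double si = sgn(i), sj = sgn(j);
    double eta = K(ii, ii) + K(jj, jj) - 2.0 * K(ii, jj);
    if (eta <= 1e-12) eta = 1e-12;

    double d;  // step along the feasible pair direction
    if (si != sj) {
      // a_i and a_j move together
      d = -(G[i] + G[j]) / eta;
      double lo = std::max(-a[i], -a[j]);
      double hi = std::min(C - a[i], C - a[j]);
      d = std::min(hi, std::max(lo, d));
      a[i] += d;
      a[j] += d;
    } else {
      // a_i up, a_j down
      d = -(G[i] - G[j]) / eta;
      double lo = std::max(-a[i], a[j] - C);
      double hi = std::min(C - a[i], a[j]);
      d = std::min(hi, std::max(lo, d));
      a[i] += d;
      a[j] -= d;
    }
    if (std::fabs(d) < 1e-15) break;  // boxed in; no progress possible

    double dbi = si * (si != sj ? d : d);        // change of beta at ii
    double dbj = sj * (si != sj ? d : -d);       // change of beta at jj
    for (int t = 0; t < N; ++t)
      G[t] += sgn(t) * (K(idx(t), ii) * dbi + K(idx(t), jj) * dbj);
  }

  NumericVector beta(n);
  for (int i2 = 0; i2 < n; ++i2) beta[i2] = a[i2] - a[i2 + n];
  double b = 0.5 * (m + M);
  return List::create(_["beta"] = beta, _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m - M, _["converged"] = (m - M) < tol);
}
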
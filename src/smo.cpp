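#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin kernel SVM dual:
//   max  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij
//   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
// Maximal-violating-pair working-set selection; stops when the KKT gap
// m(alpha) - M(alpha) drops below tol.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int iter = 0;
  double b = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    // second-order working-set selection (LIBSVM WSS2):
    // i maximizes -y_t grad_t over I_up; j minimizes the one-step objective
    // decrease -b^2/a over I_low with positive violation against i
    int i = -1, j = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      if (up && v > gmax) { gmax = v; i = t; }
    }
    double best = 0.0, delta = 0.0;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!lo) continue;
      if (v < gmin) gmin = v;
      const double bt = gmax - v;
      if (i >= 0 && bt > 0) {
        double at = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (at <= 0) at = 1e-12;
        const double score = -(bt * bt) / at;
        if (score < best) { best = score; j = t; delta = bt / at; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { b = (gmax + gmin) / 2.0; break; }

    // ai = alpha_i + y_i*delta, aj = alpha_j - y_j*delta keeps the equality
    // constraint; clip delta so both stay inside [0, C]
    double hi = delta;
    hi = std::min(hi, y[i] > 0 ? C - alpha[i] : alpha[i]);
    hi = std::min(hi, y[j] > 0 ? alpha[j] : C - alpha[j]);
    delta = std::max(0.0, hi);
    const double ai = alpha[i] + y[i] * delta;
    const double aj = alpha[j] - y[j] * delta;

    const double di = ai - alpha[i], dj = aj - alpha[j];
    if (std::fabs(di) < 1e-15 && std::fabs(dj) < 1e-15) {
      b = (gmax + gmin) / 2.0;
      break;
    }
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(t, i) * di + y[j] * K(t, j) * dj);
    alpha[i] = ai;
    alpha[j] = aj;
  }

  if (iter == max_iter) {
    // recompute b from the final violating pair bounds
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      if (((y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0)) && v > gmax)
        gmax = v;
      if (((y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C)) && v < gmin)
        gmin = v;
    }
    b = (gmax + gmin) / 2.0;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
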
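// Soft-margin C-SVC with an RBF kernel, trained by sequential minimal
// optimization on the maximal violating pair, with the b_low/b_up
// optimality gap as the stopping rule.  Deterministic; small problems
// only: the full kernel matrix is materialized.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double cost, double gamma,
                 double tol = 1e-3, int max_iter = 200000) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0;
      for (int k = 0; k < p; ++k) {
        double d = X(i, k) - X(j, k);
        s += d * d;
      }
      double v = std::exp(-gamma * s);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }
  std::vector<double> alpha(n, 0.0), f(n, 0.0); // f[i] = sum_k a_k y_k K_ki
  int iter = 0;
  double b = 0.0;
  for (; iter < max_iter; ++iter) {
    // r_i = y_i - f_i; b must lie in [max_{I_lo} r, min_{I_hi} r] at the
    // optimum, where membership follows the box status of alpha_i
    double b_low = -1e300, b_up = 1e300;
    int i_low = -1, i_up = -1;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - f[i];
      bool margin = alpha[i] > 0 && alpha[i] < cost;
      bool lo = margin || (alpha[i] <= 0 && y[i] > 0) ||
                (alpha[i] >= cost && y[i] < 0);
      bool hi = margin || (alpha[i] <= 0 && y[i] < 0) ||
                (alpha[i] >= cost && y[i] > 0);
      if (lo && r > b_low) { b_low = r; i_low = i; }
      if (hi && r < b_up) { b_up = r; i_up = i; }
    }
    if (i_low < 0 || i_up < 0 || b_low - b_up < tol) {
      b = 0.5 * (b_low + b_up);
      break;
    }
    int i = i_low, j = i_up;
    double Gi = f[i] - y[i], Gj = f[j] - y[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(cost, cost + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - cost);
      H = std::min(cost, ai_old + aj_old);
    }
    double eta = 2 * K[(size_t)i * n + j] - K[(size_t)i * n + i] -
                 K[(size_t)j * n + j];
    if (eta > -1e-12 || L >= H) { // degenerate pair: nudge j to a bound
      b = 0.5 * (b_low + b_up);
      break;
    }
    double aj = aj_old - y[j] * (Gi - Gj) / eta;
    aj = std::min(H, std::max(L, aj));
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    if (std::fabs(aj - aj_old) < 1e-12) {
      b = 0.5 * (b_low + b_up);
      break;
    }
    alpha[i] = ai;
    alpha[j] = aj;
    double dai = y[i] * (ai - ai_old), daj = y[j] * (aj - aj_old);
    for (int t = 0; t < n; ++t)
      f[t] += dai * K[(size_t)i * n + t] + daj * K[(size_t)j * n + t];
  }
  if (iter == max_iter) {
    // recompute a usable b from the final gradient state
    double b_low = -1e300, b_up = 1e300;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - f[i];
      if (alpha[i] > 0 && alpha[i] < cost) { b_low = std::max(b_low, r); b_up = std::min(b_up, r); }
    }
    b = (b_low > -1e299) ? 0.5 * (b_low + b_up) : 0.0;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}
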
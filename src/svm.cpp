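#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin C-SVC trained by sequential minimal optimization on a
// precomputed kernel matrix. Deterministic: the first multiplier is chosen
// by scanning KKT violators in index order, the second by the maximal
// |E_i - E_j| heuristic, so identical inputs give identical models.
// y must be +/-1. Returns alpha and the bias b.
// [[Rcpp::export(name = ".svc_smo_cpp")]]
List svc_smo_cpp(NumericMatrix K, NumericVector y, double C,
                 double tol, int max_passes) {
  const int n = y.size();
  NumericVector alpha(n);
  double b = 0.0;
  // error cache: E_i = f(x_i) - y_i, with f = sum_j alpha_j y_j K_ij + b
  NumericVector E(n);
  for (int i = 0; i < n; ++i) E[i] = -y[i];

  int quiet = 0, total = 0;
  while (quiet < 1 && total < max_passes) {
    ++total;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      const double ri = E[i] * y[i];
      if (!((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)))
        continue;
      // second choice: maximal step in the error cache
      int j = -1; double best = -1.0;
      for (int t = 0; t < n; ++t) {
        if (t == i) continue;
        double gap = std::abs(E[i] - E[t]);
        if (gap > best) { best = gap; j = t; }
      }
      if (j < 0) continue;
      const double ai_old = alpha[i], aj_old = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(C, C + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - C);
        H = std::min(C, ai_old + aj_old);
      }
      if (L >= H) continue;
      const double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
      if (eta >= 0) continue;
      double aj = aj_old - y[j] * (E[i] - E[j]) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::abs(aj - aj_old) < 1e-12) continue;
      const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      alpha[i] = ai; alpha[j] = aj;

      const double b1 = b - E[i] - y[i] * (ai - ai_old) * K(i, i)
                          - y[j] * (aj - aj_old) * K(i, j);
      const double b2 = b - E[j] - y[i] * (ai - ai_old) * K(i, j)
                          - y[j] * (aj - aj_old) * K(j, j);
      double b_new;
      if (ai > 0 && ai < C) b_new = b1;
      else if (aj > 0 && aj < C) b_new = b2;
      else b_new = 0.5 * (b1 + b2);
      const double db = b_new - b;
      b = b_new;
      for (int t = 0; t < n; ++t)
        E[t] += y[i] * (ai - ai_old) * K(i, t)
              + y[j] * (aj - aj_old) * K(j, t) + db;
      ++changed;
    }
    quiet = (changed == 0) ? quiet + 1 : 0;  // one clean pass ends training
  }
  return List::create(_["alpha"] = alpha, _["b"] = b);
}
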
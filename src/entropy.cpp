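#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// templates of length m taken at i = 1..N-m so that the (m+1)-length
// extension exists for every counted template; self-matches excluded by
// counting unordered pairs i < j only. Chebyshev distance, strict < r.
// Returns c(A, B): A = (m+1)-length match pairs, B = m-length match pairs.
// Pairs are enumerated through templates sorted by their first sample, so
// only candidates already matching at k = 0 are inspected further; the
// counts are identical to the naive double loop, just cheaper.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  std::vector<int> idx(nt);
  for (int i = 0; i < nt; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt - 1; ++a) {
    const int i = idx[a];
    for (int b = a + 1; b < nt && x[idx[b]] - x[i] < r; ++b) {
      const int j = idx[b];
      bool match_m = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) >= r) { match_m = false; break; }
      }
      if (match_m) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Fuzzy-entropy membership sums (Chen et al. style): templates are
// mean-centered, similarity exp(-d^nf / r) with Chebyshev d; both template
// lengths use i = 1..N-m so the counts match. Returns c(phi_m1, phi_m)
// where each phi is the mean pairwise membership at lengths m+1 and m.
// [[Rcpp::export(name = ".fuzzyen_sums_cpp")]]
NumericVector fuzzyen_sums_cpp(NumericVector x, int m, double r, double nf) {
  const int n = x.size();
  const int nt = n - m;
  // centered templates at both lengths, precomputed means
  std::vector<double> mu_m(nt), mu_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    mu_m[i] = s / m;
    mu_m1[i] = (s + x[i + m]) / (m + 1);
  }
  // extended-precision accumulation: the sums have ~nt^2/2 terms of
  // magnitude up to 1 and feed a log, so double accumulation would leak
  // ~1e-12 relative error on long epochs
  long double Sm = 0.0L, Sm1 = 0.0L;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::abs((x[i + k] - mu_m[i]) - (x[j + k] - mu_m[j]));
        if (a > dm) dm = a;
        double b = std::abs((x[i + k] - mu_m1[i]) - (x[j + k] - mu_m1[j]));
        if (b > dm1) dm1 = b;
      }
      double c = std::abs((x[i + m] - mu_m1[i]) - (x[j + m] - mu_m1[j]));
      if (c > dm1) dm1 = c;
      Sm  += std::exp(-std::pow(dm,  nf) / r);
      Sm1 += std::exp(-std::pow(dm1, nf) / r);
    }
  }
  const long double npairs = 0.5L * nt * (nt - 1);
  return NumericVector::create((double)(Sm1 / npairs),
                               (double)(Sm / npairs));
}
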
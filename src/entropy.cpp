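#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// templates i = 1..N-m for both lengths m and m+1, self-matches excluded,
// Chebyshev distance. Returns c(B, A) = matches at m, matches at m+1.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n = N - m;  // template count usable at both m and m+1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (dd <= r) A += 1.0;  // d already <= r
      }
    }
  }
  return NumericVector::create(B, A);
}

// Phi^m for approximate entropy: mean over i of log(C_i^m(r)) with
// self-matches included (Pincus convention), Chebyshev distance.
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n = N - m + 1;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (ok) ++cnt;
    }
    acc += std::log((double)cnt / (double)n);
  }
  return acc / (double)n;
}
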
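#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-pair counts for sample entropy: B = pairs of length-m templates
// within Chebyshev tolerance r, A = same for length m+1. Both use the first
// n-m templates so the two counts are comparable; self-matches excluded.
// [[Rcpp::export(name = ".sampen_counts")]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // templates with a defined (m+1)-th sample
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  return List::create(_["A"] = (double)A, _["B"] = (double)B);
}

// Cascade of second-order sections, direct form II transposed.
// sos: nsec x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi:  nsec x 2 initial conditions (already scaled by the caller).
// [[Rcpp::export(name = ".sosfilt")]]
NumericVector sosfilt(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int n = x.size(), ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = zi(s, 0), w2 = zi(s, 1);
    for (int t = 0; t < n; ++t) {
      const double xt = y[t];
      const double yt = b0 * xt + w1;
      w1 = b1 * xt - a1 * yt + w2;
      w2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}
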
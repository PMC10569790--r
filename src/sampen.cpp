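#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy, SampEn(m, r): -log(A / B) where B counts template pairs of
// length m within Chebyshev distance r (self-matches excluded) and A the same
// for length m + 1. Returns NaN when no length-m or length-(m+1) matches
// exist (the undefined case; callers flag it).
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  long long A = 0, B = 0;
  int nm = n - m; // number of length-(m+1) templates is n - m
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (A == 0 || B == 0) return R_NaN;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}
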
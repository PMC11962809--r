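// Periodised single-level DWT analysis/synthesis used by the wavelet
// denoiser. Filters are passed in so the R layer owns the coefficients.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".dwt_level_cpp")]]
List dwt_level_cpp(NumericVector x, NumericVector h, NumericVector g) {
  const int N = x.size(), L = h.size(), half = N / 2;
  NumericVector a(half), d(half);
  for (int m = 0; m < half; ++m) {
    double sa = 0, sd = 0;
    int base = 2 * m;
    for (int k = 0; k < L; ++k) {
      int idx = base + k;
      if (idx >= N) idx -= N;
      sa += h[k] * x[idx];
      sd += g[k] * x[idx];
    }
    a[m] = sa; d[m] = sd;
  }
  return List::create(Named("a") = a, Named("d") = d);
}

// [[Rcpp::export(name = ".idwt_level_cpp")]]
NumericVector idwt_level_cpp(NumericVector a, NumericVector d,
                             NumericVector h, NumericVector g) {
  const int half = a.size(), N = 2 * half, L = h.size();
  NumericVector x(N);
  for (int m = 0; m < half; ++m) {
    int base = 2 * m;
    for (int k = 0; k < L; ++k) {
      int idx = base + k;
      if (idx >= N) idx -= N;
      x[idx] += h[k] * a[m] + g[k] * d[m];
    }
  }
  return x;
}
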
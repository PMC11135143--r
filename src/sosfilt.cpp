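#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads in direct form II transposed. `zi` holds the initial
// state per section (already scaled by the first input sample when used for
// steady-state filtfilt initialization).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const int n = x.size();
  NumericVector y = clone(x);
  std::vector<double> z1(ns), z2(ns);
  for (int s = 0; s < ns; ++s) { z1[s] = zi(s, 0); z2[s] = zi(s, 1); }
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = z1[s], w2 = z2[s];
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Centered moving RMS with shrinking windows at the edges, O(n) via a
// cumulative sum of squares.
// [[Rcpp::export]]
NumericVector moving_rms_cpp(NumericVector x, int halfw) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i] * x[i];
  for (int i = 0; i < n; ++i) {
    int lo = i - halfw; if (lo < 0) lo = 0;
    int hi = i + halfw; if (hi > n - 1) hi = n - 1;
    double ms = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    out[i] = ms > 0.0 ? std::sqrt(ms) : 0.0;
  }
  return out;
}
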
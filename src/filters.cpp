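#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward IIR filtering of each column of X (zero initial state in
// both directions).  Used for the line-noise notch, where the biquad's edge
// transient is a handful of samples against recordings of ~10^6 samples.
// [[Rcpp::export(name = ".iir_filtfilt_mat")]]
NumericMatrix iir_filtfilt_mat(NumericVector b, NumericVector a,
                               NumericMatrix X) {
  const int n = X.nrow(), nc = X.ncol();
  const int nb = b.size(), na = a.size();
  if (na < 1 || a[0] == 0.0) stop("a[1] must be non-zero");
  NumericMatrix Y(n, nc);
  std::vector<double> bn(nb), an(na);
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) an[i] = a[i] / a[0];
  std::vector<double> w(n);
  for (int c = 0; c < nc; ++c) {
    // forward
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nb && k <= i; ++k) acc += bn[k] * X(i - k, c);
      for (int k = 1; k < na && k <= i; ++k) acc -= an[k] * w[i - k];
      w[i] = acc;
    }
    // backward
    for (int i = n - 1; i >= 0; --i) {
      double acc = 0.0;
      for (int k = 0; k < nb && i + k < n; ++k) acc += bn[k] * w[i + k];
      for (int k = 1; k < na && i + k < n; ++k) acc -= an[k] * Y(i + k, c);
      Y(i, c) = acc;
    }
  }
  return Y;
}

// Zero-phase FIR filtering of each column of X with a symmetric (linear
// phase) kernel h, compensating the (L-1)/2 group delay, and keeping every
// q-th output sample (polyphase decimation; q = 1 gives plain zero-phase
// filtering).  Samples outside the input are treated as zero.
// [[Rcpp::export(name = ".fir_zerophase_mat")]]
NumericMatrix fir_zerophase_mat(NumericVector h, NumericMatrix X, int q) {
  const int n = X.nrow(), nc = X.ncol(), L = h.size();
  if (q < 1) stop("q must be >= 1");
  if (L % 2 == 0) stop("kernel length must be odd (type-I linear phase)");
  const int D = (L - 1) / 2;
  const int m = (n + q - 1) / q;
  NumericMatrix Y(m, nc);
  for (int c = 0; c < nc; ++c) {
    const double *x = &X(0, c);
    for (int j = 0; j < m; ++j) {
      const int centre = j * q + D;  // index into the delayed full convolution
      int k0 = centre - (n - 1); if (k0 < 0) k0 = 0;
      int k1 = centre; if (k1 > L - 1) k1 = L - 1;
      double acc = 0.0;
      for (int k = k0; k <= k1; ++k) acc += h[k] * x[centre - k];
      Y(j, c) = acc;
    }
  }
  return Y;
}
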
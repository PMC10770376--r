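#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Direct-form-II-transposed IIR step with explicit initial state.
static void df2t_filter(const std::vector<double>& bb,
                        const std::vector<double>& aa,
                        std::vector<double>& z,
                        const double* x, double* y, int n) {
  const int m = static_cast<int>(bb.size());
  const int ord = m - 1;
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bb[0] * xt + z[0];
    for (int k = 0; k < ord - 1; ++k) {
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    }
    z[ord - 1] = bb[m - 1] * xt - aa[m - 1] * yt;
    y[t] = yt;
  }
}

// Zero-phase forward-backward filtering of every column of x with
// odd-reflection padding and step-matched initial conditions (the
// standard filtfilt transient-suppression schedule). `zi` is the unit
// steady-state filter state; `pad` the reflection length.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericVector zi, NumericMatrix x, int pad) {
  const int m = std::max(b.size(), a.size());
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a[0];
  const int nt = x.nrow(), ns = x.ncol();
  const int ext = nt + 2 * pad;
  NumericMatrix y(nt, ns);
  std::vector<double> buf(ext), f1(ext), f2(ext), z(m - 1);
  for (int j = 0; j < ns; ++j) {
    const double x0 = x(0, j), xl = x(nt - 1, j);
    for (int t = 0; t < pad; ++t) buf[t] = 2.0 * x0 - x(pad - t, j);
    for (int t = 0; t < nt; ++t) buf[pad + t] = x(t, j);
    for (int t = 0; t < pad; ++t) buf[pad + nt + t] = 2.0 * xl - x(nt - 2 - t, j);
    for (int k = 0; k < m - 1; ++k) z[k] = zi[k] * buf[0];
    df2t_filter(bb, aa, z, buf.data(), f1.data(), ext);
    std::reverse(f1.begin(), f1.end());
    for (int k = 0; k < m - 1; ++k) z[k] = zi[k] * f1[0];
    df2t_filter(bb, aa, z, f1.data(), f2.data(), ext);
    std::reverse(f2.begin(), f2.end());
    for (int t = 0; t < nt; ++t) y(t, j) = f2[pad + t];
  }
  return y;
}

// Plain IIR filtering (zero initial state) of every column.
// [[Rcpp::export]]
NumericMatrix cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericMatrix x) {
  const int m = std::max(b.size(), a.size());
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a[0];
  const int nt = x.nrow(), ns = x.ncol();
  NumericMatrix y(nt, ns);
  std::vector<double> z(m - 1);
  std::vector<double> xin(nt), yout(nt);
  for (int j = 0; j < ns; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < nt; ++t) xin[t] = x(t, j);
    df2t_filter(bb, aa, z, xin.data(), yout.data(), nt);
    for (int t = 0; t < nt; ++t) y(t, j) = yout[t];
  }
  return y;
}
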
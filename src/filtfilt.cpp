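#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, one pass, with initial state zi*x0.
static void lfilter(const std::vector<double>& b, const std::vector<double>& a,
                    const double* x, double* y, int n,
                    const std::vector<double>& zi, double x0) {
  int m = (int)b.size() - 1;          // filter order (a, b same length, a[0]=1)
  std::vector<double> z(m);
  for (int k = 0; k < m; ++k) z[k] = zi[k] * x0;
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int k = 0; k < m - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
}

// Zero-phase forward-backward filtering of each column of x.
// Odd (antisymmetric) edge extension of length npad on both ends; each pass
// starts from the steady state for the segment mean (zi scaled), which
// suppresses both DC-offset and slow-pole start-up transients.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericVector b_, NumericVector a_,
                           NumericMatrix x, int npad, NumericVector zi_) {
  int n = x.nrow(), nc = x.ncol();
  std::vector<double> b(b_.begin(), b_.end()), a(a_.begin(), a_.end());
  std::vector<double> zi(zi_.begin(), zi_.end());
  if (npad >= n) npad = n - 1;
  int ne = n + 2 * npad;
  NumericMatrix out(n, nc);
  std::vector<double> ext(ne), tmp(ne);
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    // odd extension: 2*x[0] - x[k] reversed at the start, same at the end
    for (int k = 0; k < npad; ++k) ext[k] = 2.0 * col[0] - col[npad - k];
    for (int k = 0; k < n; ++k) ext[npad + k] = col[k];
    for (int k = 0; k < npad; ++k) ext[npad + n + k] = 2.0 * col[n - 1] - col[n - 2 - k];
    double m1 = 0.0;
    for (int k = 0; k < ne; ++k) m1 += ext[k];
    m1 /= ne;
    lfilter(b, a, ext.data(), tmp.data(), ne, zi, m1);
    std::reverse(tmp.begin(), tmp.end());
    double m2 = 0.0;
    for (int k = 0; k < ne; ++k) m2 += tmp[k];
    m2 /= ne;
    lfilter(b, a, tmp.data(), ext.data(), ne, zi, m2);
    std::reverse(ext.begin(), ext.end());
    for (int k = 0; k < n; ++k) out(k, j) = ext[npad + k];
  }
  return out;
}
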
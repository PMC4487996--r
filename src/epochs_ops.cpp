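#include <Rcpp.h>
using namespace Rcpp;

// data is an n x ch x tr array (column-major). All helpers return fresh
// objects; the inputs are never modified in place.

// [[Rcpp::export(name = ".avg_ref")]]
NumericVector avg_ref(NumericVector data, int n, int ch, int tr) {
  NumericVector out(clone(data));
  std::vector<double> m(n);
  for (int t = 0; t < tr; ++t) {
    double* base = &out[(R_xlen_t)t * n * ch];
    std::fill(m.begin(), m.end(), 0.0);
    for (int c = 0; c < ch; ++c) {
      const double* col = base + (R_xlen_t)c * n;
      for (int i = 0; i < n; ++i) m[i] += col[i];
    }
    for (int i = 0; i < n; ++i) m[i] /= ch;
    for (int c = 0; c < ch; ++c) {
      double* col = base + (R_xlen_t)c * n;
      for (int i = 0; i < n; ++i) col[i] -= m[i];
    }
  }
  out.attr("dim") = data.attr("dim");
  out.attr("dimnames") = data.attr("dimnames");
  return out;
}

// [[Rcpp::export(name = ".baseline")]]
NumericVector baseline(NumericVector data, int n, int ch, int tr,
                       IntegerVector sel) {
  NumericVector out(clone(data));
  int ns = sel.size();
  for (int t = 0; t < tr; ++t) {
    double* base = &out[(R_xlen_t)t * n * ch];
    for (int c = 0; c < ch; ++c) {
      double* col = base + (R_xlen_t)c * n;
      double m = 0.0;
      for (int k = 0; k < ns; ++k) m += col[sel[k] - 1];
      m /= ns;
      for (int i = 0; i < n; ++i) col[i] -= m;
    }
  }
  out.attr("dim") = data.attr("dim");
  out.attr("dimnames") = data.attr("dimnames");
  return out;
}

// [[Rcpp::export(name = ".max_abs_trial")]]
NumericVector max_abs_trial(NumericVector data, int n, int ch, int tr) {
  NumericVector out(tr);
  for (int t = 0; t < tr; ++t) {
    const double* base = &data[(R_xlen_t)t * n * ch];
    double mx = 0.0;
    for (R_xlen_t k = 0; k < (R_xlen_t)n * ch; ++k) {
      double v = std::fabs(base[k]);
      if (v > mx) mx = v;
    }
    out[t] = mx;
  }
  return out;
}
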
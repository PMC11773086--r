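#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with zero initial conditions.
// b, a: transfer-function coefficients (a[0] must be non-zero).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0), w(nw, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double yt = bb[0] * x[t] + w[0];
    for (int k = 0; k < nw - 1; ++k) {
      w[k] = bb[k + 1] * x[t] - aa[k + 1] * yt + w[k + 1];
    }
    y[t] = yt;
  }
  return y;
}
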
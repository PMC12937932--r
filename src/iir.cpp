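#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial conditions.
// b, a: coefficient vectors (a[0] == 1 assumed; caller normalizes).
// zi: initial state of length max(len(a), len(b)) - 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nord = std::max(na, nb) - 1;
  int n = x.size();
  std::vector<double> bb(nord + 1, 0.0), aa(nord + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nord, 0.0);
  for (int i = 0; i < nord && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nord - 1; ++k) {
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    }
    z[nord - 1] = bb[nord] * xt - aa[nord] * yt;
    y[t] = yt;
  }
  return y;
}
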
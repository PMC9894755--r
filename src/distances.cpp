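#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Canberra distance between rows of X, with the |x| + |y|
// denominator convention (as used for standardized metabolome vectors).
// A coordinate where |x| + |y| == 0 contributes 0, keeping distances
// finite on sparse or centered data.
// [[Rcpp::export(rng = false)]]
NumericMatrix canberra_pairwise(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double xi = X(i, k), xj = X(j, k);
        double denom = std::abs(xi) + std::abs(xj);
        if (denom > 0.0) s += std::abs(xi - xj) / denom;
      }
      D(i, j) = s;
      D(j, i) = s;
    }
  }
  return D;
}
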
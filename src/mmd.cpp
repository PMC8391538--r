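#include <Rcpp.h>
using namespace Rcpp;

// Mean Gaussian-kernel value over all (row of X, row of Y) pairs:
// (1/(mn)) sum_{i,j} exp(-||x_i - y_j||^2 / (2 l^2)).
// The three terms of the biased (V-statistic) MMD^2 estimator are all
// instances of this sum, so the hot loop lives here.
// [[Rcpp::export]]
double gauss_kernel_mean_cpp(NumericMatrix X, NumericMatrix Y, double bandwidth) {
  const int m = X.nrow(), n = Y.nrow(), d = X.ncol();
  const double inv2l2 = 1.0 / (2.0 * bandwidth * bandwidth);
  double s = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double t = X(i, k) - Y(j, k);
        d2 += t * t;
      }
      s += std::exp(-d2 * inv2l2);
    }
  }
  return s / (static_cast<double>(m) * static_cast<double>(n));
}
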
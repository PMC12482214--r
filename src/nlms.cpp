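#include <Rcpp.h>
using namespace Rcpp;

// Normalized-LMS adaptive FIR filter.
//
// y(u) = sum_{i=0}^{taps-1} w_i(u) x(u - i), weights updated toward the
// reference d by w <- w + mu * e * x_vec / (eps + ||x_vec||^2).
// Strictly causal in x; zero-initialized weights. The per-sample update is
// inherently sequential, hence compiled.
// [[Rcpp::export]]
List nlms_filter_cpp(NumericVector x, NumericVector d, int taps,
                     double mu, double eps) {
  int n = x.size();
  if (d.size() != n) stop("x and d must have equal length");
  if (taps < 1) stop("taps must be >= 1");
  NumericVector y(n);
  std::vector<double> w(taps, 0.0);
  for (int u = 0; u < n; ++u) {
    double yn = 0.0, norm = eps;
    int imax = std::min(taps - 1, u);
    for (int i = 0; i <= imax; ++i) {
      double xi = x[u - i];
      yn += w[i] * xi;
      norm += xi * xi;
    }
    y[u] = yn;
    double g = mu * (d[u] - yn) / norm;
    for (int i = 0; i <= imax; ++i) w[i] += g * x[u - i];
  }
  NumericVector wf(w.begin(), w.end());
  return List::create(_["y"] = y, _["w"] = wf);
}
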
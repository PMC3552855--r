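#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian convolution with reflected boundaries; kernel radius
// 4*sigma. Used by the synthetic-image renderer as the optical PSF.

// [[Rcpp::export(name = ".gaussian_blur")]]
NumericMatrix gaussian_blur(const NumericMatrix& x, double sigma) {
  if (sigma <= 0) return clone(x);
  const int nr = x.nrow(), nc = x.ncol();
  const int rad = (int) std::ceil(4.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)          // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * x(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)          // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}
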
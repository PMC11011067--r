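#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Separable 2D convolution with reflecting boundaries. Used for Gaussian
// smoothing and Gaussian-derivative (Hessian) filtering on small images,
// where direct spatial convolution beats FFT-based filtering.

static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// [[Rcpp::export(name = ".conv_sep")]]
NumericMatrix conv_sep(NumericMatrix img, NumericVector krow,
                       NumericVector kcol) {
  int nr = img.nrow(), nc = img.ncol();
  int hr = krow.size() / 2, hc = kcol.size() / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // convolve along rows (first dimension)
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      double acc = 0.0;
      for (int k = 0; k < krow.size(); k++)
        acc += krow[k] * img(reflect(i + k - hr, nr), j);
      tmp(i, j) = acc;
    }
  }
  // convolve along columns (second dimension)
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      double acc = 0.0;
      for (int k = 0; k < kcol.size(); k++)
        acc += kcol[k] * tmp(i, reflect(j + k - hc, nc));
      out(i, j) = acc;
    }
  }
  return out;
}
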
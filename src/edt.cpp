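#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform, Felzenszwalb & Huttenlocher
// (2012) lower-envelope-of-parabolas algorithm, separable over rows/columns.
// Needed because the perinuclear band is defined by exact per-pixel
// distances (d_nuc / (d_nuc + d_mem)) and must agree with a brute-force
// nearest-pixel evaluation to the last pixel.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix target) {
  // squared Euclidean distance from every pixel to the nearest TRUE pixel
  int nr = target.nrow(), nc = target.ncol();
  const double INF = 1e20;
  NumericMatrix d(nr, nc);
  // initialise: 0 at target pixels, INF elsewhere
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      d(i, j) = target(i, j) ? 0.0 : INF;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // transform along columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = d(i, j);
    dt1d(f, out, nr);
    for (int i = 0; i < nr; i++) d(i, j) = out[i];
  }
  // transform along rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = d(i, j);
    dt1d(f, out, nc);
    for (int j = 0; j < nc; j++) d(i, j) = out[j];
  }
  return d;
}
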
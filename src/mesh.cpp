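#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Nearest and second-nearest lattice-seed distances for mesh rendering.
// Seeds sit on a square (jittered) or hexagonal lattice indexed by
// (i, j) in [-m, m]^2; a pixel's nearest seeds always lie in the 3x3
// lattice neighbourhood of its own node.

// [[Rcpp::export(name = ".mesh_nearest_cpp")]]
List mesh_nearest_cpp(NumericVector u, NumericVector v,
                      NumericMatrix jx, NumericMatrix jy,
                      double s, double row_pitch, bool hex, int m) {
  int n = u.size();
  int n_side = 2 * m + 1;
  NumericVector d1(n), d2(n);
  IntegerVector lab(n);
  for (int p = 0; p < n; p++) {
    double up = u[p], vp = v[p];
    int i0 = (int) std::lround(up / row_pitch);
    double off0 = hex ? (std::abs(i0) % 2) * s / 2.0 : 0.0;
    int j0 = (int) std::lround((vp - off0) / s);
    double b1 = R_PosInf, b2 = R_PosInf;
    int best = 0;
    for (int di = -1; di <= 1; di++) {
      for (int dj = -1; dj <= 1; dj++) {
        int ii = i0 + di, jj = j0 + dj;
        if (ii < -m) ii = -m; if (ii > m) ii = m;
        if (jj < -m) jj = -m; if (jj > m) jj = m;
        int idx = (ii + m) + (jj + m) * n_side; // 0-based linear index
        double su = ii * row_pitch + jx[idx];
        double off = hex ? (std::abs(ii) % 2) * s / 2.0 : 0.0;
        double sv = jj * s + off + jy[idx];
        double dd = (up - su) * (up - su) + (vp - sv) * (vp - sv);
        if (idx + 1 == best) continue; // same seed revisited (clamped)
        if (dd < b1) {
          b2 = b1; b1 = dd; best = idx + 1;
        } else if (dd < b2) {
          b2 = dd;
        }
      }
    }
    d1[p] = std::sqrt(b1);
    d2[p] = std::sqrt(b2);
    lab[p] = best;
  }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["lab"] = lab);
}
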
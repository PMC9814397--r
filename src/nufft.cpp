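#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gridding step of a type-1 NUFFT: spread complex point sources onto an
// oversampled periodic grid with the exponential-of-semicircle kernel
//   phi(t) = exp(beta * (sqrt(1 - (t/c)^2) - 1)),  |t| <= c = width/2.
// gx (column) and gy (row) are source positions in grid units in [0, ng).
// [[Rcpp::export(rng = false)]]
ComplexMatrix es_spread2(NumericVector gy, NumericVector gx, ComplexVector w,
                         int ngr, int ngc, int width, double beta) {
  const R_xlen_t n = gx.size();
  if (gy.size() != n || w.size() != n)
    stop("gx, gy and w must have equal length");
  std::vector<double> re((size_t)ngr * ngc, 0.0), im((size_t)ngr * ngc, 0.0);
  const double c = width / 2.0;
  std::vector<double> wx(width), wy(width);
  std::vector<int> rows(width), cols(width);
  const Rcomplex* wp = COMPLEX(w);

  for (R_xlen_t j = 0; j < n; ++j) {
    const double gxj = gx[j], gyj = gy[j];
    const int ix0 = (int)std::ceil(gxj - c);
    const int iy0 = (int)std::ceil(gyj - c);
    for (int t = 0; t < width; ++t) {
      double u = (gxj - (ix0 + t)) / c;
      wx[t] = (u > -1.0 && u < 1.0)
                  ? std::exp(beta * (std::sqrt(1.0 - u * u) - 1.0)) : 0.0;
      double v = (gyj - (iy0 + t)) / c;
      wy[t] = (v > -1.0 && v < 1.0)
                  ? std::exp(beta * (std::sqrt(1.0 - v * v) - 1.0)) : 0.0;
      int col = (ix0 + t) % ngc; if (col < 0) col += ngc;
      int row = (iy0 + t) % ngr; if (row < 0) row += ngr;
      cols[t] = col; rows[t] = row;
    }
    const double wr = wp[j].r, wi = wp[j].i;
    for (int a = 0; a < width; ++a) {
      if (wx[a] == 0.0) continue;
      const double ar = wr * wx[a], ai = wi * wx[a];
      const size_t base = (size_t)cols[a] * ngr;
      for (int b = 0; b < width; ++b) {
        re[base + rows[b]] += ar * wy[b];
        im[base + rows[b]] += ai * wy[b];
      }
    }
  }

  ComplexMatrix out(ngr, ngc);
  Rcomplex* op = COMPLEX(out);
  for (size_t i = 0; i < re.size(); ++i) {
    op[i].r = re[i];
    op[i].i = im[i];
  }
  return out;
}
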
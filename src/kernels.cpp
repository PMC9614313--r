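#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sampling of `img` at continuous 0-based pixel coordinates
// (sx = column, sy = row).  Samples falling outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_bilinear(NumericMatrix img, NumericVector sx,
                                  NumericVector sy, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const R_xlen_t n = sx.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = sx[i], y = sy[i];
    if (ISNAN(x) || ISNAN(y) || x < 0.0 || y < 0.0 ||
        x > nc - 1.0 || y > nr - 1.0) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    if (x0 == nc - 1) x0--;          // clamp so x0+1 stays in range
    if (y0 == nr - 1) y0--;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    const double fx = x - x0, fy = y - y0;
    const double v00 = img(y0, x0),     v01 = img(y0, x0 + 1);
    const double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
    out[i] = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
             fy       * ((1 - fx) * v10 + fx * v11);
  }
  return out;
}

// Nearest-neighbour sampling for label grids (same coordinate convention).
// [[Rcpp::export]]
IntegerVector cpp_sample_nearest(IntegerMatrix img, NumericVector sx,
                                 NumericVector sy, int fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const R_xlen_t n = sx.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = sx[i], y = sy[i];
    if (ISNAN(x) || ISNAN(y)) { out[i] = fill; continue; }
    const int xi = (int)std::lround(x), yi = (int)std::lround(y);
    if (xi < 0 || yi < 0 || xi >= nc || yi >= nr) out[i] = fill;
    else out[i] = img(yi, xi);
  }
  return out;
}

// Separable Gaussian blur with replicate boundary handling.
// sigma in pixels; sigma <= 0 returns the input unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double &w : k) w /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0;
        if (rr >= nr) rr = nr - 1;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  // along columns (horizontal)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = 0;
        if (cc >= nc) cc = nc - 1;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}
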
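#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Detector sampling and per-pixel filters used by the reconstruction and
// pre-processing paths. Coordinates are 0-based element-center coordinates
// (column u, row v); samples outside the image contribute 0.

// [[Rcpp::export(name = ".bilinearSampleCpp")]]
NumericVector bilinearSampleCpp(NumericMatrix img, NumericVector u,
                                NumericVector v) {
  const int nr = img.nrow(), nc = img.ncol();
  const R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    const double uu = u[k], vv = v[k];
    if (!R_finite(uu) || !R_finite(vv)) { out[k] = 0.0; continue; }
    const double fu = std::floor(uu), fv = std::floor(vv);
    const int iu = (int)fu, iv = (int)fv;
    if (iu < -1 || iu > nc - 1 || iv < -1 || iv > nr - 1) { out[k] = 0.0; continue; }
    const double du = uu - fu, dv = vv - fv;
    double acc = 0.0;
    // contributions from the 4 surrounding pixels, zero outside
    if (iv >= 0 && iu >= 0)          acc += (1 - dv) * (1 - du) * img(iv, iu);
    if (iv >= 0 && iu + 1 <= nc - 1) acc += (1 - dv) * du * img(iv, iu + 1);
    if (iv + 1 <= nr - 1 && iu >= 0) acc += dv * (1 - du) * img(iv + 1, iu);
    if (iv + 1 <= nr - 1 && iu + 1 <= nc - 1) acc += dv * du * img(iv + 1, iu + 1);
    out[k] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".linearSampleCpp")]]
NumericVector linearSampleCpp(NumericVector row, NumericVector u) {
  const int n = row.size();
  const R_xlen_t m = u.size();
  NumericVector out(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    const double uu = u[k];
    if (!R_finite(uu)) { out[k] = 0.0; continue; }
    const double fu = std::floor(uu);
    const int iu = (int)fu;
    if (iu < -1 || iu > n - 1) { out[k] = 0.0; continue; }
    const double du = uu - fu;
    double acc = 0.0;
    if (iu >= 0) acc += (1 - du) * row[iu];
    if (iu + 1 <= n - 1) acc += du * row[iu + 1];
    out[k] = acc;
  }
  return out;
}

// Conditional median filter: replace a pixel by the median of its
// (2r+1)^2 neighborhood iff it deviates from that median by more than
// `threshold` in the selected direction (1 bright, -1 dark, 0 both).
// `padded` is the reflect-padded input; output has the interior size.
// [[Rcpp::export(name = ".removeOutliersCpp")]]
NumericMatrix removeOutliersCpp(NumericMatrix padded, int r, double threshold,
                                int direction) {
  const int nr = padded.nrow() - 2 * r, nc = padded.ncol() - 2 * r;
  const int w = 2 * r + 1, nn = w * w;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(nn);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = 0; dj < w; ++dj)
        for (int di = 0; di < w; ++di)
          buf[k++] = padded(i + di, j + dj);
      std::nth_element(buf.begin(), buf.begin() + nn / 2, buf.end());
      double med = buf[nn / 2];
      if (nn % 2 == 0) {
        // even count (never happens for square windows, kept for safety)
        double lo = *std::max_element(buf.begin(), buf.begin() + nn / 2);
        med = 0.5 * (med + lo);
      }
      const double x = padded(i + r, j + r);
      const double dev = x - med;
      bool replace = false;
      if (direction >= 0 && dev > threshold) replace = true;
      if (direction <= 0 && -dev > threshold) replace = true;
      out(i, j) = replace ? med : x;
    }
  }
  return out;
}

// Reference (naive) non-local means on a reflect-padded image. Patch
// distance is the mean squared difference over the (2p+1)^2 patch, weights
// exp(-max(D2 - 2 sigma^2, 0)/h^2); the center pixel gets the maximum
// neighbor weight. Output has the interior size (padded minus s+p border).
// [[Rcpp::export(name = ".nlmNaiveCpp")]]
NumericMatrix nlmNaiveCpp(NumericMatrix padded, int s, int p, double h,
                          double sigma) {
  const int off = s + p;
  const int nr = padded.nrow() - 2 * off, nc = padded.ncol() - 2 * off;
  NumericMatrix out(nr, nc);
  const double npatch = (2.0 * p + 1) * (2.0 * p + 1);
  const double h2 = h * h, s2 = 2.0 * sigma * sigma;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int ci = i + off, cj = j + off;
      double wsum = 0.0, vsum = 0.0, wmax = 0.0;
      for (int dj = -s; dj <= s; ++dj) {
        for (int di = -s; di <= s; ++di) {
          if (di == 0 && dj == 0) continue;
          double d2 = 0.0;
          for (int b = -p; b <= p; ++b)
            for (int a = -p; a <= p; ++a) {
              const double diff = padded(ci + a, cj + b) -
                                  padded(ci + di + a, cj + dj + b);
              d2 += diff * diff;
            }
          d2 /= npatch;
          double arg = d2 - s2;
          if (arg < 0) arg = 0;
          const double w = std::exp(-arg / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          vsum += w * padded(ci + di, cj + dj);
        }
      }
      if (wmax <= 0) wmax = 1.0;
      wsum += wmax;
      vsum += wmax * padded(ci, cj);
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
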
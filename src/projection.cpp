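#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at (x, y) in pixel coordinates centred on the grid
// centre; zero outside the grid.
static inline double sampleBilinear(const NumericMatrix &img, double x, double y) {
  int n = img.nrow();                      // square grid
  double cx = 0.5 * (n - 1);
  double fx = x + cx, fy = y + cx;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
  if (ix < -1 || ix > n - 1 || iy < -1 || iy > n - 1) return 0.0;
  double dx = fx - ix, dy = fy - iy;
  double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
  if (ix >= 0 && iy >= 0)         v00 = img(ix, iy);
  if (ix >= 0 && iy + 1 <= n - 1) v01 = img(ix, iy + 1);
  if (ix + 1 <= n - 1 && iy >= 0) v10 = img(ix + 1, iy);
  if (ix + 1 <= n - 1 && iy + 1 <= n - 1) v11 = img(ix + 1, iy + 1);
  return (1 - dx) * (1 - dy) * v00 + (1 - dx) * dy * v01 +
         dx * (1 - dy) * v10 + dx * dy * v11;
}

// Parallel-beam ray-driven forward projection.
// img: N x N attenuation per pixel; angles in radians; detector offsets in
// pixel units spaced by detSpacing and centred on the rotation axis.
// Returns nAngles x nDet line integrals (in pixel-length units).
// [[Rcpp::export]]
NumericMatrix cpp_forward_project_parallel(NumericMatrix img, NumericVector angles,
                                           int nDet, double detSpacing, double step) {
  int n = img.nrow();
  int nAng = angles.size();
  double tMax = 0.75 * n;                  // covers the inscribed diagonal
  NumericMatrix out(nAng, nDet);
  for (int a = 0; a < nAng; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int d = 0; d < nDet; ++d) {
      double s = (d - 0.5 * (nDet - 1)) * detSpacing;
      double px = s * ca, py = s * sa;     // closest point on ray to origin
      double acc = 0.0;
      for (double t = -tMax; t <= tMax; t += step) {
        acc += sampleBilinear(img, px - t * sa, py + t * ca);
      }
      out(a, d) = acc * step;
    }
  }
  return out;
}

// Fan-beam (flat detector) forward projection. Source rotates on a circle of
// radius sod (pixel units); detector offsets u (pixel units at the detector)
// on a flat detector at distance sdd from the source, perpendicular to the
// central ray. betas are source angles in radians.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project_fan(NumericMatrix img, NumericVector betas,
                                      int nDet, double detSpacing,
                                      double sod, double sdd, double step) {
  int n = img.nrow();
  int nAng = betas.size();
  double rMax = 0.75 * n;
  NumericMatrix out(nAng, nDet);
  for (int a = 0; a < nAng; ++a) {
    double cb = std::cos(betas[a]), sb = std::sin(betas[a]);
    double sx = sod * cb, sy = sod * sb;
    for (int d = 0; d < nDet; ++d) {
      double u = (d - 0.5 * (nDet - 1)) * detSpacing;
      // detector element position
      double dxp = -sdd * cb - u * sb + sx;
      double dyp = -sdd * sb + u * cb + sy;
      double rx = dxp - sx, ry = dyp - sy;
      double norm = std::sqrt(rx * rx + ry * ry);
      rx /= norm; ry /= norm;
      double acc = 0.0;
      // march only through the neighbourhood of the object
      for (double t = sod - rMax; t <= sod + rMax; t += step) {
        acc += sampleBilinear(img, sx + t * rx, sy + t * ry);
      }
      out(a, d) = acc * step;
    }
  }
  return out;
}

// Backprojection of filtered parallel projections onto an N x N grid.
// filtered: nAngles x nDet. Output must be scaled by pi / (2 * nAngles) and
// by 1/detSpacing in the caller.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_parallel(NumericMatrix filtered, NumericVector angles,
                                       int n, double detSpacing) {
  int nAng = angles.size();
  int nDet = filtered.ncol();
  double c0 = 0.5 * (n - 1);
  double d0 = 0.5 * (nDet - 1);
  NumericMatrix out(n, n);
  for (int a = 0; a < nAng; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int j = 0; j < n; ++j) {
      double y = j - c0;
      for (int i = 0; i < n; ++i) {
        double x = i - c0;
        double s = (x * ca + y * sa) / detSpacing + d0;
        int is = (int)std::floor(s);
        if (is < 0 || is >= nDet - 1) continue;
        double ds = s - is;
        out(i, j) += (1 - ds) * filtered(a, is) + ds * filtered(a, is + 1);
      }
    }
  }
  return out;
}

// Box (uniform) filter partial sums over all fully-contained k x k windows.
// Returns (H-k+1) x (W-k+1) window sums; used by the SSIM local statistics.
// [[Rcpp::export]]
NumericMatrix cpp_boxsum_valid(NumericMatrix x, int k) {
  int h = x.nrow(), w = x.ncol();
  int oh = h - k + 1, ow = w - k + 1;
  NumericMatrix out(oh, ow);
  // column-wise running sums then row-wise
  NumericMatrix tmp(oh, w);
  for (int j = 0; j < w; ++j) {
    double s = 0;
    for (int i = 0; i < k; ++i) s += x(i, j);
    tmp(0, j) = s;
    for (int i = 1; i < oh; ++i) {
      s += x(i + k - 1, j) - x(i - 1, j);
      tmp(i, j) = s;
    }
  }
  for (int i = 0; i < oh; ++i) {
    double s = 0;
    for (int j = 0; j < k; ++j) s += tmp(i, j);
    out(i, 0) = s;
    for (int j = 1; j < ow; ++j) {
      s += tmp(i, j + k - 1) - tmp(i, j - 1);
      out(i, j) = s;
    }
  }
  return out;
}
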
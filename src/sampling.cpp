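#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Image coordinate convention (shared with the R side): origin at the
// top-left corner, x to the right, y downwards, and the centre of the pixel
// in column j, row i (1-based) at (j - 0.5, i - 0.5).

// Assign every pixel centre to its nearest station centre (Euclidean metric,
// ties broken by the lowest station index). Exact: uses a uniform bucket
// grid with expanding ring search, so it scales to large grids without the
// O(pixels x stations) blow-up.
// [[Rcpp::export]]
IntegerMatrix cpp_nn_assign(NumericVector sx, NumericVector sy,
                            int width, int height) {
  const int n = sx.size();
  if (n < 1) stop("at least one station is required");
  double xmin = 0.0, ymin = 0.0, xmax = width, ymax = height;
  for (int s = 0; s < n; ++s) {
    if (!R_finite(sx[s]) || !R_finite(sy[s])) stop("non-finite station centre");
    xmin = std::min(xmin, sx[s]); xmax = std::max(xmax, sx[s]);
    ymin = std::min(ymin, sy[s]); ymax = std::max(ymax, sy[s]);
  }
  double g = std::sqrt((xmax - xmin + 1.0) * (ymax - ymin + 1.0) / n);
  if (g < 0.5) g = 0.5;
  const int nbx = (int)std::floor((xmax - xmin) / g) + 1;
  const int nby = (int)std::floor((ymax - ymin) / g) + 1;
  std::vector< std::vector<int> > buckets((size_t)nbx * nby);
  for (int s = 0; s < n; ++s) {
    int bx = std::min(nbx - 1, (int)std::floor((sx[s] - xmin) / g));
    int by = std::min(nby - 1, (int)std::floor((sy[s] - ymin) / g));
    buckets[(size_t)by * nbx + bx].push_back(s); // index-ascending within bucket
  }
  const int maxring = std::max(nbx, nby);
  IntegerMatrix out(height, width);
  for (int j = 0; j < width; ++j) {
    double px = j + 0.5;
    int pbx = std::min(nbx - 1, std::max(0, (int)std::floor((px - xmin) / g)));
    for (int i = 0; i < height; ++i) {
      double py = i + 0.5;
      int pby = std::min(nby - 1, std::max(0, (int)std::floor((py - ymin) / g)));
      double best = R_PosInf;
      int besti = -1;
      for (int k = 0; k <= maxring; ++k) {
        // any point in a bucket k rings away is at distance >= (k-1)*g
        // (strict <, so an exact tie at the bound still gets the id check)
        if (besti >= 0 && k >= 2 &&
            best < (double)(k - 1) * g * (double)(k - 1) * g) break;
        int bx0 = pbx - k, bx1 = pbx + k, by0 = pby - k, by1 = pby + k;
        for (int by = by0; by <= by1; ++by) {
          if (by < 0 || by >= nby) continue;
          bool edge_row = (by == by0 || by == by1);
          int step = edge_row ? 1 : (bx1 - bx0 > 0 ? bx1 - bx0 : 1);
          for (int bx = bx0; bx <= bx1; bx += step) {
            if (bx < 0 || bx >= nbx) continue;
            const std::vector<int>& b = buckets[(size_t)by * nbx + bx];
            for (size_t q = 0; q < b.size(); ++q) {
              int s = b[q];
              double dx = sx[s] - px, dy = sy[s] - py;
              double d2 = dx * dx + dy * dy;
              if (d2 < best || (d2 == best && s < besti)) {
                best = d2; besti = s;
              }
            }
          }
        }
      }
      out(i, j) = besti + 1;
    }
  }
  return out;
}

// Gaussian acceptance-angle average (one gray plane, one station set).
// Weight of pixel i for a station with acceptance angle rho (FWHM of the
// angular sensitivity): exp(-2.77 * (alpha_i / rho)^2), alpha_i the off-axis
// angle of the pixel. Scanning mode: the eye sits on the normal through the
// station centre at distance d, alpha_i = atan(r/d) with r the in-plane
// distance. Fixed mode: the eye sits at distance d on the normal through
// (x0, y0) and alpha_i is the angle between the eye->station and eye->pixel
// vectors. The sum is truncated at alpha_i > trunc_mult * rho; trunc_mult
// <= 0 disables truncation (exact Eq. over the whole plane).
// Returns NaN for a station whose truncated support contains no pixel.
// [[Rcpp::export]]
NumericVector cpp_gauss_sample(NumericMatrix plane,
                               NumericVector sx, NumericVector sy,
                               NumericVector rho_deg, double d,
                               bool fixed_mode, double x0, double y0,
                               double trunc_mult) {
  const int h = plane.nrow(), w = plane.ncol(), n = sx.size();
  const double DEG = M_PI / 180.0;
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    const double rho = rho_deg[s] * DEG;
    if (!(rho > 0)) stop("acceptance angle must be positive");
    const double cx = sx[s], cy = sy[s];
    double sw = 0.0, swc = 0.0;
    // pass 0: truncated sum; pass 1 (only if the truncated support held no
    // pixel): untruncated, so truncation stays a pure optimisation
    for (int pass = 0; pass < 2; ++pass) {
    const double amax = (pass == 0 && trunc_mult > 0) ? trunc_mult * rho : -1.0;
    int j0 = 0, j1 = w - 1, i0 = 0, i1 = h - 1;
    if (amax > 0 && amax < 1.55) {
      // conservative bounding box of the truncation region on the plane
      double R = -1.0;
      if (!fixed_mode) {
        R = d * std::tan(amax);
      } else {
        double rs = std::hypot(cx - x0, cy - y0);
        double ts = std::atan2(rs, d);
        if (ts + amax < 1.55) {
          // support = interior of a cone/plane ellipse containing the
          // station; its diameter bounds the distance to any support point
          R = d * (std::tan(ts + amax) - std::tan(ts - amax));
        }
      }
      if (R > 0) {
        j0 = std::max(0, (int)std::floor(cx - R - 0.5));
        j1 = std::min(w - 1, (int)std::ceil(cx + R - 0.5));
        i0 = std::max(0, (int)std::floor(cy - R - 0.5));
        i1 = std::min(h - 1, (int)std::ceil(cy + R - 0.5));
      }
    }
    const double kk = -2.77 / (rho * rho);
    if (!fixed_mode) {
      for (int j = j0; j <= j1; ++j) {
        const double dx = (j + 0.5) - cx;
        for (int i = i0; i <= i1; ++i) {
          const double dy = (i + 0.5) - cy;
          const double a = std::atan(std::sqrt(dx * dx + dy * dy) / d);
          if (amax > 0 && a > amax) continue;
          const double wt = std::exp(kk * a * a);
          sw += wt; swc += wt * plane(i, j);
        }
      }
    } else {
      const double ax = cx - x0, ay = cy - y0, az = -d;
      const double na = std::sqrt(ax * ax + ay * ay + az * az);
      for (int j = j0; j <= j1; ++j) {
        const double bx = (j + 0.5) - x0;
        for (int i = i0; i <= i1; ++i) {
          const double by = (i + 0.5) - y0;
          double c = (ax * bx + ay * by + az * -d) /
            (na * std::sqrt(bx * bx + by * by + d * d));
          if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
          const double a = std::acos(c);
          if (amax > 0 && a > amax) continue;
          const double wt = std::exp(kk * a * a);
          sw += wt; swc += wt * plane(i, j);
        }
      }
    }
    if (sw > 0 || trunc_mult <= 0) break;
    } // pass
    out[s] = sw > 0 ? swc / sw : R_NaN;
  }
  return out;
}
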
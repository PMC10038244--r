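#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// ---- segment distance ------------------------------------------------------

static inline double seg_seg_dist2(double ax, double ay, double bx, double by,
                                   double cx, double cy, double dx, double dy) {
  // squared distance between segments AB and CD
  double ux = bx - ax, uy = by - ay;
  double vx = dx - cx, vy = dy - cy;
  double wx = ax - cx, wy = ay - cy;
  double a = ux * ux + uy * uy;
  double b = ux * vx + uy * vy;
  double c = vx * vx + vy * vy;
  double d = ux * wx + uy * wy;
  double e = vx * wx + vy * wy;
  double D = a * c - b * b;
  double sN, sD = D, tN, tD = D;
  const double EPS = 1e-14;
  if (D < EPS) { sN = 0.0; sD = 1.0; tN = e; tD = c; }
  else {
    sN = b * e - c * d; tN = a * e - b * d;
    if (sN < 0.0) { sN = 0.0; tN = e; tD = c; }
    else if (sN > sD) { sN = sD; tN = e + b; tD = c; }
  }
  if (tN < 0.0) {
    tN = 0.0;
    if (-d < 0.0) sN = 0.0;
    else if (-d > a) sN = sD;
    else { sN = -d; sD = a; }
  } else if (tN > tD) {
    tN = tD;
    if ((-d + b) < 0.0) sN = 0.0;
    else if ((-d + b) > a) sN = sD;
    else { sN = -d + b; sD = a; }
  }
  double s = (std::fabs(sD) < EPS) ? 0.0 : sN / sD;
  double t = (std::fabs(tD) < EPS) ? 0.0 : tN / tD;
  double px = wx + s * ux - t * vx;
  double py = wy + s * uy - t * vy;
  return px * px + py * py;
}

struct Seg { double x0, y0, x1, y1, bx0, by0, bx1, by1; };

static void paths_to_segs(List paths, bool closed, std::vector<Seg>& segs) {
  for (int k = 0; k < paths.size(); k++) {
    List p = paths[k];
    NumericVector x = p["x"], y = p["y"];
    int n = x.size();
    if (n < 2) continue;
    int m = closed ? n : n - 1;
    for (int i = 0; i < m; i++) {
      int j = (i + 1) % n;
      Seg s;
      s.x0 = x[i]; s.y0 = y[i]; s.x1 = x[j]; s.y1 = y[j];
      s.bx0 = std::min(s.x0, s.x1); s.bx1 = std::max(s.x0, s.x1);
      s.by0 = std::min(s.y0, s.y1); s.by1 = std::max(s.y0, s.y1);
      segs.push_back(s);
    }
  }
}

// [[Rcpp::export]]
double rcpp_min_dist_paths(List pathsA, List pathsB, bool closedA, bool closedB,
                           double cap) {
  std::vector<Seg> A, B;
  paths_to_segs(pathsA, closedA, A);
  paths_to_segs(pathsB, closedB, B);
  if (A.empty() || B.empty()) return R_PosInf;
  double best2 = R_PosInf;
  double cap2 = R_FINITE(cap) ? cap * cap : R_PosInf;
  for (size_t i = 0; i < A.size(); i++) {
    const Seg& a = A[i];
    for (size_t j = 0; j < B.size(); j++) {
      const Seg& b = B[j];
      // bbox lower bound prune
      double dx = std::max(0.0, std::max(b.bx0 - a.bx1, a.bx0 - b.bx1));
      double dy = std::max(0.0, std::max(b.by0 - a.by1, a.by0 - b.by1));
      double lb2 = dx * dx + dy * dy;
      if (lb2 >= best2 || lb2 > cap2) continue;
      double d2 = seg_seg_dist2(a.x0, a.y0, a.x1, a.y1, b.x0, b.y0, b.x1, b.y1);
      if (d2 < best2) {
        best2 = d2;
        if (best2 == 0.0) return 0.0;
      }
    }
  }
  if (best2 > cap2) return R_PosInf;
  return std::sqrt(best2);
}

// ---- rasterization ---------------------------------------------------------

// Rasterize a set of polygon features (union semantics across features,
// even-odd within a feature) onto a nx x ny pixel grid with origin (x0, y0)
// and pixel size res; a pixel is set when its CENTER is covered.
// 'features' is a list of features; each feature is a list of rings
// (list(x=, y=)).
// [[Rcpp::export]]
LogicalVector rcpp_scanline_mask(List features, int nx, int ny,
                                 double x0, double y0, double res) {
  LogicalVector out(static_cast<R_xlen_t>(nx) * ny, false);
  std::vector<double> xs;
  for (int f = 0; f < features.size(); f++) {
    List rings = features[f];
    // gather edges of this feature
    std::vector<double> ex0, ey0, ex1, ey1;
    for (int r = 0; r < rings.size(); r++) {
      List ring = rings[r];
      NumericVector x = ring["x"], y = ring["y"];
      int n = x.size();
      for (int i = 0; i < n; i++) {
        int j = (i + 1) % n;
        ex0.push_back(x[i]); ey0.push_back(y[i]);
        ex1.push_back(x[j]); ey1.push_back(y[j]);
      }
    }
    for (int iy = 0; iy < ny; iy++) {
      double yc = y0 + (iy + 0.5) * res;
      xs.clear();
      for (size_t e = 0; e < ex0.size(); e++) {
        double ya = ey0[e], yb = ey1[e];
        if ((ya <= yc && yb > yc) || (yb <= yc && ya > yc)) {
          double t = (yc - ya) / (yb - ya);
          xs.push_back(ex0[e] + t * (ex1[e] - ex0[e]));
        }
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        // pixels with center in (xs[k], xs[k+1])
        int i0 = (int)std::ceil((xs[k] - x0) / res - 0.5);
        int i1 = (int)std::floor((xs[k + 1] - x0) / res - 0.5);
        if (i0 < 0) i0 = 0;
        if (i1 >= nx) i1 = nx - 1;
        for (int ix = i0; ix <= i1; ix++)
          out[static_cast<R_xlen_t>(iy) * nx + ix] = true;
      }
    }
  }
  return out;
}

// Exact distance band around line segments: marks pixels whose center lies
// within 'maxd' of any segment of any path. Paths are open (list(x=, y=)).
// [[Rcpp::export]]
LogicalVector rcpp_seg_band(List paths, int nx, int ny,
                            double x0, double y0, double res, double maxd) {
  LogicalVector out(static_cast<R_xlen_t>(nx) * ny, false);
  double maxd2 = maxd * maxd;
  std::vector<Seg> segs;
  paths_to_segs(paths, false, segs);
  for (size_t s = 0; s < segs.size(); s++) {
    const Seg& sg = segs[s];
    int ix0 = (int)std::floor((sg.bx0 - maxd - x0) / res - 0.5);
    int ix1 = (int)std::ceil((sg.bx1 + maxd - x0) / res);
    int iy0 = (int)std::floor((sg.by0 - maxd - y0) / res - 0.5);
    int iy1 = (int)std::ceil((sg.by1 + maxd - y0) / res);
    if (ix0 < 0) ix0 = 0;
    if (iy0 < 0) iy0 = 0;
    if (ix1 >= nx) ix1 = nx - 1;
    if (iy1 >= ny) iy1 = ny - 1;
    double ux = sg.x1 - sg.x0, uy = sg.y1 - sg.y0;
    double len2 = ux * ux + uy * uy;
    for (int iy = iy0; iy <= iy1; iy++) {
      double py = y0 + (iy + 0.5) * res;
      for (int ix = ix0; ix <= ix1; ix++) {
        R_xlen_t idx = static_cast<R_xlen_t>(iy) * nx + ix;
        if (out[idx]) continue;
        double px = x0 + (ix + 0.5) * res;
        double t = 0.0;
        if (len2 > 0) {
          t = ((px - sg.x0) * ux + (py - sg.y0) * uy) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        double dx = px - (sg.x0 + t * ux), dy = py - (sg.y0 + t * uy);
        if (dx * dx + dy * dy <= maxd2) out[idx] = true;
      }
    }
  }
  return out;
}

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
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

// Squared distance (in pixel units) from every pixel to the nearest 'true'
// pixel of the mask. Empty-mask pixels are "far" (>= 1e18 squared pixels).
// A large finite sentinel is used instead of +Inf because the lower-envelope
// recursion is undefined for Inf - Inf.
// [[Rcpp::export]]
NumericVector rcpp_edt_sq(LogicalVector mask, int nx, int ny) {
  const double BIG = 1e18;
  NumericVector out(static_cast<R_xlen_t>(nx) * ny);
  std::vector<double> f(std::max(nx, ny)), d(std::max(nx, ny)), z(std::max(nx, ny) + 1);
  std::vector<int> v(std::max(nx, ny));
  std::vector<double> tmp(static_cast<size_t>(nx) * ny);
  for (R_xlen_t i = 0; i < out.size(); i++)
    tmp[i] = mask[i] ? 0.0 : BIG;
  // along y (columns)
  for (int ix = 0; ix < nx; ix++) {
    bool any = false;
    for (int iy = 0; iy < ny; iy++) {
      f[iy] = tmp[static_cast<size_t>(iy) * nx + ix];
      if (f[iy] == 0.0) any = true;
    }
    if (!any) continue;  // stays BIG
    edt_1d(f, d, v, z, ny);
    for (int iy = 0; iy < ny; iy++)
      tmp[static_cast<size_t>(iy) * nx + ix] = d[iy];
  }
  // along x (rows)
  for (int iy = 0; iy < ny; iy++) {
    for (int ix = 0; ix < nx; ix++)
      f[ix] = tmp[static_cast<size_t>(iy) * nx + ix];
    edt_1d(f, d, v, z, nx);
    for (int ix = 0; ix < nx; ix++)
      out[static_cast<R_xlen_t>(iy) * nx + ix] = d[ix];
  }
  return out;
}
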
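#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Planar geometry kernel for SAP mapping: signed areas, Sutherland-Hodgman
// clipping against convex windows, mass-conserving rasterization onto an
// axis-aligned equal-area grid, and point-in-polygon tests. Rings are Nx2
// matrices of projected coordinates in metres, not closed (first vertex is
// not repeated at the end).

typedef std::vector<double> dvec;

static double signed_area(const dvec &x, const dvec &y) {
  const size_t n = x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (size_t i = 0, j = n - 1; i < n; j = i++)
    a += x[j] * y[i] - x[i] * y[j];
  return 0.5 * a;
}

// Clip polygon (x,y) by the half-plane on the left of directed edge
// (ex0,ey0)->(ex1,ey1). Standard Sutherland-Hodgman step.
static void clip_halfplane(const dvec &x, const dvec &y,
                           double ex0, double ey0, double ex1, double ey1,
                           dvec &ox, dvec &oy) {
  ox.clear(); oy.clear();
  const size_t n = x.size();
  if (n == 0) return;
  const double dx = ex1 - ex0, dy = ey1 - ey0;
  double ps = dx * (y[n - 1] - ey0) - dy * (x[n - 1] - ex0);
  for (size_t i = 0; i < n; ++i) {
    const double cs = dx * (y[i] - ey0) - dy * (x[i] - ex0);
    const size_t j = (i == 0) ? n - 1 : i - 1;
    if (cs >= 0.0) {
      if (ps < 0.0) { // entering: add intersection
        const double t = ps / (ps - cs);
        ox.push_back(x[j] + t * (x[i] - x[j]));
        oy.push_back(y[j] + t * (y[i] - y[j]));
      }
      ox.push_back(x[i]); oy.push_back(y[i]);
    } else if (ps >= 0.0) { // leaving: add intersection
      const double t = ps / (ps - cs);
      ox.push_back(x[j] + t * (x[i] - x[j]));
      oy.push_back(y[j] + t * (y[i] - y[j]));
    }
    ps = cs;
  }
}

static void mat_to_vecs(const NumericMatrix &m, dvec &x, dvec &y, bool force_ccw) {
  const int n = m.nrow();
  x.resize(n); y.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = m(i, 0); y[i] = m(i, 1); }
  if (force_ccw && signed_area(x, y) < 0.0) {
    std::reverse(x.begin(), x.end());
    std::reverse(y.begin(), y.end());
  }
}

// Area of subject ring clipped to axis-aligned rectangle [x0,x1]x[y0,y1].
static double clip_rect_area_impl(const dvec &sx, const dvec &sy,
                                  double x0, double y0, double x1, double y1) {
  dvec ax = sx, ay = sy, bx, by;
  clip_halfplane(ax, ay, x0, y0, x1, y0, bx, by); // bottom
  clip_halfplane(bx, by, x1, y0, x1, y1, ax, ay); // right
  clip_halfplane(ax, ay, x1, y1, x0, y1, bx, by); // top
  clip_halfplane(bx, by, x0, y1, x0, y0, ax, ay); // left
  const double a = signed_area(ax, ay);
  return a > 0.0 ? a : 0.0;
}

//' @noRd
// [[Rcpp::export]]
double cpp_ring_area(NumericMatrix ring) {
  dvec x, y;
  mat_to_vecs(ring, x, y, false);
  return std::fabs(signed_area(x, y));
}

// [[Rcpp::export]]
double cpp_clip_rect_area(NumericMatrix ring, double x0, double y0,
                          double x1, double y1) {
  dvec sx, sy;
  mat_to_vecs(ring, sx, sy, true);
  return clip_rect_area_impl(sx, sy, x0, y0, x1, y1);
}

// Area of subject ring clipped to a convex ring. Exact for simple subjects.
// [[Rcpp::export]]
double cpp_convex_clip_area(NumericMatrix subject, NumericMatrix clip) {
  dvec sx, sy, cx, cy;
  mat_to_vecs(subject, sx, sy, true);
  mat_to_vecs(clip, cx, cy, true);
  dvec ax = sx, ay = sy, bx, by;
  const size_t nc = cx.size();
  bool in_a = true;
  for (size_t i = 0, j = nc - 1; i < nc; j = i++) {
    if (in_a) clip_halfplane(ax, ay, cx[j], cy[j], cx[i], cy[i], bx, by);
    else      clip_halfplane(bx, by, cx[j], cy[j], cx[i], cy[i], ax, ay);
    in_a = !in_a;
  }
  const double a = in_a ? signed_area(ax, ay) : signed_area(bx, by);
  return a > 0.0 ? a : 0.0;
}

// Rasterize one ring onto grid with origin (gx0, gy0), square cells of side
// `cell`, nx columns, ny rows. Returns an ny x nx matrix. mode 0 ("exact
// area"): covered fraction of each cell, conserving total ring area; mode 1
// ("cell center"): 1 where the cell centre lies inside the ring.
// Row r (1-based in R) corresponds to y in [gy0+(r-1)*cell, gy0+r*cell).
// [[Rcpp::export]]
NumericMatrix cpp_rasterize_ring(NumericMatrix ring, double gx0, double gy0,
                                 double cell, int nx, int ny, int mode) {
  dvec sx, sy;
  mat_to_vecs(ring, sx, sy, true);
  NumericMatrix out(ny, nx);
  const size_t n = sx.size();
  if (n < 3) return out;
  double xmin = sx[0], xmax = sx[0], ymin = sy[0], ymax = sy[0];
  for (size_t i = 1; i < n; ++i) {
    xmin = std::min(xmin, sx[i]); xmax = std::max(xmax, sx[i]);
    ymin = std::min(ymin, sy[i]); ymax = std::max(ymax, sy[i]);
  }
  int c0 = std::max(0, (int)std::floor((xmin - gx0) / cell));
  int c1 = std::min(nx - 1, (int)std::floor((xmax - gx0) / cell));
  int r0 = std::max(0, (int)std::floor((ymin - gy0) / cell));
  int r1 = std::min(ny - 1, (int)std::floor((ymax - gy0) / cell));
  const double ca = cell * cell;
  if (mode == 0) {
    for (int r = r0; r <= r1; ++r) {
      const double y0 = gy0 + r * cell, y1 = y0 + cell;
      for (int c = c0; c <= c1; ++c) {
        const double x0 = gx0 + c * cell, x1 = x0 + cell;
        const double a = clip_rect_area_impl(sx, sy, x0, y0, x1, y1);
        if (a > 0.0) out(r, c) = a / ca;
      }
    }
  } else {
    for (int r = r0; r <= r1; ++r) {
      const double yc = gy0 + (r + 0.5) * cell;
      for (int c = c0; c <= c1; ++c) {
        const double xc = gx0 + (c + 0.5) * cell;
        // even-odd rule
        bool inside = false;
        for (size_t i = 0, j = n - 1; i < n; j = i++) {
          if (((sy[i] > yc) != (sy[j] > yc)) &&
              (xc < (sx[j] - sx[i]) * (yc - sy[i]) / (sy[j] - sy[i]) + sx[i]))
            inside = !inside;
        }
        if (inside) out(r, c) = 1.0;
      }
    }
  }
  return out;
}

// Even-odd point-in-ring test for a set of points.
// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericVector px, NumericVector py,
                                 NumericMatrix ring) {
  dvec sx, sy;
  mat_to_vecs(ring, sx, sy, false);
  const size_t n = sx.size();
  const int np = px.size();
  LogicalVector out(np);
  for (int k = 0; k < np; ++k) {
    const double x = px[k], y = py[k];
    bool inside = false;
    for (size_t i = 0, j = n - 1; i < n; j = i++) {
      if (((sy[i] > y) != (sy[j] > y)) &&
          (x < (sx[j] - sx[i]) * (y - sy[i]) / (sy[j] - sy[i]) + sx[i]))
        inside = !inside;
    }
    out[k] = inside;
  }
  return out;
}

static bool seg_intersect_proper(double ax, double ay, double bx, double by,
                                 double cx, double cy, double dx, double dy) {
  const double d1 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  const double d2 = (bx - ax) * (dy - ay) - (by - ay) * (dx - ax);
  const double d3 = (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx);
  const double d4 = (dx - cx) * (by - cy) - (dy - cy) * (bx - cx);
  return ((d1 > 0) != (d2 > 0)) && (d1 != 0) && (d2 != 0) &&
         ((d3 > 0) != (d4 > 0)) && (d3 != 0) && (d4 != 0);
}

// TRUE when the ring is simple: no two non-adjacent edges properly cross.
// [[Rcpp::export]]
bool cpp_ring_simple(NumericMatrix ring) {
  dvec x, y;
  mat_to_vecs(ring, x, y, false);
  const int n = (int)x.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      const int j2 = (j + 1) % n;
      if (i == j || i2 == j || i == j2) continue;
      if (seg_intersect_proper(x[i], y[i], x[i2], y[i2],
                               x[j], y[j], x[j2], y[j2]))
        return false;
    }
  }
  return true;
}
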
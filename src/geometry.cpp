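#include <Rcpp.h>
using namespace Rcpp;

static inline double pt_seg_dist(double px, double py,
                                 double x1, double y1, double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - x1) * dx + (py - y1) * dy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double ex = x1 + t * dx - px, ey = y1 + t * dy - py;
  return std::sqrt(ex * ex + ey * ey);
}

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool segs_intersect(double ax1, double ay1, double ax2, double ay2,
                           double bx1, double by1, double bx2, double by2) {
  double d1 = cross3(bx1, by1, bx2, by2, ax1, ay1);
  double d2 = cross3(bx1, by1, bx2, by2, ax2, ay2);
  double d3 = cross3(ax1, ay1, ax2, ay2, bx1, by1);
  double d4 = cross3(ax1, ay1, ax2, ay2, bx2, by2);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  return false; // collinear/touching handled by endpoint distances (-> 0)
}

// Min distance from each point to a set of segments (segs: m x 4, x1 y1 x2 y2).
// [[Rcpp::export]]
NumericVector cpp_dist_points_segments(NumericMatrix pts, NumericMatrix segs) {
  int n = pts.nrow(), m = segs.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1);
    for (int j = 0; j < m; ++j) {
      double d = pt_seg_dist(px, py, segs(j, 0), segs(j, 1), segs(j, 2), segs(j, 3));
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    out[i] = best;
  }
  return out;
}

// Min distance from each point to a set of points (ref: m x 2).
// [[Rcpp::export]]
NumericVector cpp_dist_points_points(NumericMatrix pts, NumericMatrix ref) {
  int n = pts.nrow(), m = ref.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1);
    for (int j = 0; j < m; ++j) {
      double dx = px - ref(j, 0), dy = py - ref(j, 1);
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Minimum edge-to-edge distance between two segment sets; 0 if any pair crosses.
// [[Rcpp::export]]
double cpp_dist_segments_segments(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      if (segs_intersect(a(i, 0), a(i, 1), a(i, 2), a(i, 3),
                         b(j, 0), b(j, 1), b(j, 2), b(j, 3))) return 0.0;
      double d = pt_seg_dist(a(i, 0), a(i, 1), b(j, 0), b(j, 1), b(j, 2), b(j, 3));
      double d2 = pt_seg_dist(a(i, 2), a(i, 3), b(j, 0), b(j, 1), b(j, 2), b(j, 3));
      if (d2 < d) d = d2;
      double d3 = pt_seg_dist(b(j, 0), b(j, 1), a(i, 0), a(i, 1), a(i, 2), a(i, 3));
      if (d3 < d) d = d3;
      double d4 = pt_seg_dist(b(j, 2), b(j, 3), a(i, 0), a(i, 1), a(i, 2), a(i, 3));
      if (d4 < d) d = d4;
      if (d < best) best = d;
      if (best == 0.0) return 0.0;
    }
  }
  return best;
}

// Even-odd ray-cast point-in-polygon; poly is an open ring (k x 2).
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), k = poly.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    bool inside = false;
    for (int j = 0, l = k - 1; j < k; l = j++) {
      double xj = poly(j, 0), yj = poly(j, 1);
      double xl = poly(l, 0), yl = poly(l, 1);
      if (((yj > py) != (yl > py)) &&
          (px < (xl - xj) * (py - yj) / (yl - yj) + xj)) inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}
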
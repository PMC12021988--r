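#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Planar geometry kernels for islet/nucleus polygons.
// Polygons are n x 2 matrices of vertices in um, first vertex NOT repeated;
// edges wrap around from the last vertex back to the first.

static inline double ptSegDist2(double px, double py,
                                double ax, double ay,
                                double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool onSegment(double ax, double ay, double bx, double by,
                             double px, double py) {
  return std::min(ax, bx) <= px && px <= std::max(ax, bx) &&
         std::min(ay, by) <= py && py <= std::max(ay, by);
}

// proper or touching intersection of segments AB and CD
static bool segIntersect(double ax, double ay, double bx, double by,
                         double cx, double cy, double dx, double dy) {
  double d1 = orient(cx, cy, dx, dy, ax, ay);
  double d2 = orient(cx, cy, dx, dy, bx, by);
  double d3 = orient(ax, ay, bx, by, cx, cy);
  double d4 = orient(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  if (d1 == 0 && onSegment(cx, cy, dx, dy, ax, ay)) return true;
  if (d2 == 0 && onSegment(cx, cy, dx, dy, bx, by)) return true;
  if (d3 == 0 && onSegment(ax, ay, bx, by, cx, cy)) return true;
  if (d4 == 0 && onSegment(ax, ay, bx, by, dx, dy)) return true;
  return false;
}

static double segSegDist(double ax, double ay, double bx, double by,
                         double cx, double cy, double dx, double dy) {
  if (segIntersect(ax, ay, bx, by, cx, cy, dx, dy)) return 0.0;
  double d2 = ptSegDist2(ax, ay, cx, cy, dx, dy);
  d2 = std::min(d2, ptSegDist2(bx, by, cx, cy, dx, dy));
  d2 = std::min(d2, ptSegDist2(cx, cy, ax, ay, bx, by));
  d2 = std::min(d2, ptSegDist2(dx, dy, ax, ay, bx, by));
  return std::sqrt(d2);
}

// [[Rcpp::export]]
double cpp_polygon_min_distance(NumericMatrix P, NumericMatrix Q) {
  int n = P.nrow(), m = Q.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double ax = P(i, 0), ay = P(i, 1), bx = P(i2, 0), by = P(i2, 1);
    for (int j = 0; j < m; ++j) {
      int j2 = (j + 1) % m;
      double d = segSegDist(ax, ay, bx, by,
                            Q(j, 0), Q(j, 1), Q(j2, 0), Q(j2, 1));
      if (d < best) {
        best = d;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_point_polygon_distance(NumericMatrix pts, NumericMatrix poly) {
  int np = pts.nrow(), n = poly.nrow();
  NumericVector out(np);
  for (int k = 0; k < np; ++k) {
    double px = pts(k, 0), py = pts(k, 1);
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      int i2 = (i + 1) % n;
      double d2 = ptSegDist2(px, py, poly(i, 0), poly(i, 1),
                             poly(i2, 0), poly(i2, 1));
      if (d2 < best) best = d2;
    }
    out[k] = std::sqrt(best);
  }
  return out;
}

// Even-odd rule; points exactly on the boundary count as inside.
// [[Rcpp::export]]
IntegerVector cpp_points_in_polygon(NumericMatrix pts, NumericMatrix poly) {
  int np = pts.nrow(), n = poly.nrow();
  IntegerVector out(np);
  for (int k = 0; k < np; ++k) {
    double px = pts(k, 0), py = pts(k, 1);
    bool inside = false, boundary = false;
    for (int i = 0; i < n && !boundary; ++i) {
      int i2 = (i + 1) % n;
      double ax = poly(i, 0), ay = poly(i, 1);
      double bx = poly(i2, 0), by = poly(i2, 1);
      if (orient(ax, ay, bx, by, px, py) == 0.0 &&
          onSegment(ax, ay, bx, by, px, py)) {
        boundary = true;
        break;
      }
      if ((ay > py) != (by > py)) {
        double xcross = ax + (py - ay) / (by - ay) * (bx - ax);
        if (px < xcross) inside = !inside;
      }
    }
    out[k] = (inside || boundary) ? 1 : 0;
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_polygon_is_simple(NumericMatrix P) {
  int n = P.nrow();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      // skip adjacent edges (they share a vertex by construction)
      if (j == i || j2 == i || j == i2) continue;
      if (segIntersect(P(i, 0), P(i, 1), P(i2, 0), P(i2, 1),
                       P(j, 0), P(j, 1), P(j2, 0), P(j2, 1))) return false;
    }
  }
  return true;
}

// Hard-core (minimum-separation) rejection sampler inside a polygon.
// Draws from R's RNG so results follow set.seed(). Points are kept at least
// `margin` from the polygon boundary and `rmin` from each other; gives up on
// a point after maxAttempts consecutive rejections.
// [[Rcpp::export]]
NumericMatrix cpp_place_hardcore(NumericMatrix poly, int nTarget,
                                 double rmin, double margin,
                                 int maxAttempts) {
  int n = poly.nrow();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, poly(i, 0));
    xmax = std::max(xmax, poly(i, 0));
    ymin = std::min(ymin, poly(i, 1));
    ymax = std::max(ymax, poly(i, 1));
  }
  std::vector<double> ax, ay;
  ax.reserve(nTarget);
  ay.reserve(nTarget);
  double rmin2 = rmin * rmin;
  GetRNGstate();
  for (int k = 0; k < nTarget; ++k) {
    bool placed = false;
    for (int att = 0; att < maxAttempts; ++att) {
      double px = R::runif(xmin, xmax);
      double py = R::runif(ymin, ymax);
      // containment (even-odd)
      bool inside = false;
      for (int i = 0; i < n; ++i) {
        int i2 = (i + 1) % n;
        double vax = poly(i, 0), vay = poly(i, 1);
        double vbx = poly(i2, 0), vby = poly(i2, 1);
        if ((vay > py) != (vby > py)) {
          double xcross = vax + (py - vay) / (vby - vay) * (vbx - vax);
          if (px < xcross) inside = !inside;
        }
      }
      if (!inside) continue;
      if (margin > 0.0) {
        double b2 = R_PosInf;
        for (int i = 0; i < n; ++i) {
          int i2 = (i + 1) % n;
          double d2 = ptSegDist2(px, py, poly(i, 0), poly(i, 1),
                                 poly(i2, 0), poly(i2, 1));
          if (d2 < b2) b2 = d2;
        }
        if (b2 < margin * margin) continue;
      }
      bool clash = false;
      for (size_t q = 0; q < ax.size(); ++q) {
        double dx = ax[q] - px, dy = ay[q] - py;
        if (dx * dx + dy * dy < rmin2) {
          clash = true;
          break;
        }
      }
      if (clash) continue;
      ax.push_back(px);
      ay.push_back(py);
      placed = true;
      break;
    }
    if (!placed) break; // polygon saturated at this separation
  }
  PutRNGstate();
  NumericMatrix out(ax.size(), 2);
  for (size_t q = 0; q < ax.size(); ++q) {
    out(q, 0) = ax[q];
    out(q, 1) = ay[q];
  }
  return out;
}
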
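#include <Rcpp.h>
using namespace Rcpp;

// Even-odd (ray-crossing) test. Points lying exactly on an edge may land on
// either side; callers resolve the frontier with the distance rule, so the
// ambiguity never reaches zone labels.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericMatrix poly) {
  const int n = px.size(), m = poly.nrow();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    bool c = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      const double xj = poly(j, 0), yj = poly(j, 1);
      const double xk = poly(k, 0), yk = poly(k, 1);
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        c = !c;
    }
    inside[i] = c;
  }
  return inside;
}

// Minimum Euclidean distance from each point to the closed polygonal chain.
// [[Rcpp::export]]
NumericVector cpp_dist_to_polygon(NumericVector px, NumericVector py,
                                  NumericMatrix poly) {
  const int n = px.size(), m = poly.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    double best = R_PosInf;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      const double x1 = poly(k, 0), y1 = poly(k, 1);
      const double ex = poly(j, 0) - x1, ey = poly(j, 1) - y1;
      const double L2 = ex * ex + ey * ey;
      double t = L2 > 0 ? ((x - x1) * ex + (y - y1) * ey) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      const double dx = x - (x1 + t * ex), dy = y - (y1 + t * ey);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  auto orient = [](double px, double py, double qx, double qy,
                   double rx, double ry) {
    const double v = (qx - px) * (ry - py) - (qy - py) * (rx - px);
    return (v > 0) - (v < 0);
  };
  const int o1 = orient(ax, ay, bx, by, cx, cy);
  const int o2 = orient(ax, ay, bx, by, dx, dy);
  const int o3 = orient(cx, cy, dx, dy, ax, ay);
  const int o4 = orient(cx, cy, dx, dy, bx, by);
  return (o1 != o2 && o3 != o4);
}

// True when the closed polygon has no proper edge crossings between
// non-adjacent edges (shared vertices of adjacent edges are allowed).
// [[Rcpp::export]]
bool cpp_polygon_is_simple(NumericMatrix poly) {
  const int m = poly.nrow();
  for (int i = 0; i < m; ++i) {
    const int i2 = (i + 1) % m;
    for (int j = i + 1; j < m; ++j) {
      const int j2 = (j + 1) % m;
      if (j == i || j2 == i || j == i2) continue;  // adjacent edges
      if (seg_intersect(poly(i, 0), poly(i, 1), poly(i2, 0), poly(i2, 1),
                        poly(j, 0), poly(j, 1), poly(j2, 0), poly(j2, 1)))
        return false;
    }
  }
  return true;
}
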
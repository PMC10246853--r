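// Fast 2D polygon primitives used by the packing and rasterization layers.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericMatrix poly) {
  const int n = poly.nrow(), m = px.size();
  LogicalVector inside(m);
  for (int q = 0; q < m; ++q) {
    bool in = false;
    double x = px[q], y = py[q];
    for (int j = 0, k = n - 1; j < n; k = j++) {
      double xj = poly(j, 0), yj = poly(j, 1);
      double xk = poly(k, 0), yk = poly(k, 1);
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        in = !in;
    }
    inside[q] = in;
  }
  return inside;
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_polygon(NumericVector px, NumericVector py,
                                  NumericMatrix poly) {
  const int n = poly.nrow(), m = px.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double x = px[q], y = py[q], best = R_PosInf;
    for (int j = 0, k = n - 1; j < n; k = j++) {
      double ax = poly(k, 0), ay = poly(k, 1);
      double bx = poly(j, 0), by = poly(j, 1);
      double vx = bx - ax, vy = by - ay;
      double L2 = vx * vx + vy * vy;
      double t = L2 > 0 ? ((x - ax) * vx + (y - ay) * vy) / L2 : 0.0;
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      double dx = x - (ax + t * vx), dy = y - (ay + t * vy);
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// Minimum boundary gap between two polygons; 0 if they overlap.
// [[Rcpp::export]]
double cpp_polygon_gap(NumericMatrix a, NumericMatrix b) {
  LogicalVector ain = cpp_points_in_polygon(a(_, 0), a(_, 1), b);
  for (int i = 0; i < ain.size(); ++i) if (ain[i]) return 0.0;
  LogicalVector bin = cpp_points_in_polygon(b(_, 0), b(_, 1), a);
  for (int i = 0; i < bin.size(); ++i) if (bin[i]) return 0.0;
  NumericVector d1 = cpp_dist_to_polygon(a(_, 0), a(_, 1), b);
  NumericVector d2 = cpp_dist_to_polygon(b(_, 0), b(_, 1), a);
  double best = R_PosInf;
  for (int i = 0; i < d1.size(); ++i) if (d1[i] < best) best = d1[i];
  for (int i = 0; i < d2.size(); ++i) if (d2[i] < best) best = d2[i];
  return best;
}
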
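// Grow-and-relax fascicle packing: shrunken shape templates are inflated
// to full size while sequential (Gauss-Seidel) constraint projection
// pushes violating pairs apart, pulls strays inside the epineurium, and
// tries small template rotations when a shape jams.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Poly {
  std::vector<double> x, y;
};

static void fill_poly(const NumericMatrix& tmpl, double scale, double rot_deg,
                      double cx, double cy, Poly& out) {
  const int m = tmpl.nrow();
  out.x.resize(m); out.y.resize(m);
  double c = std::cos(rot_deg * M_PI / 180.0), s = std::sin(rot_deg * M_PI / 180.0);
  for (int i = 0; i < m; ++i) {
    double px = tmpl(i, 0) * scale, py = tmpl(i, 1) * scale;
    out.x[i] = cx + c * px - s * py;
    out.y[i] = cy + s * px + c * py;
  }
}

static bool point_in(const std::vector<double>& X, const std::vector<double>& Y,
                     double x, double y) {
  const int n = X.size();
  bool in = false;
  for (int j = 0, k = n - 1; j < n; k = j++) {
    if (((Y[j] > y) != (Y[k] > y)) &&
        (x < (X[k] - X[j]) * (y - Y[j]) / (Y[k] - Y[j]) + X[j]))
      in = !in;
  }
  return in;
}

static double dist_boundary(const std::vector<double>& X,
                            const std::vector<double>& Y,
                            double x, double y) {
  const int n = X.size();
  double best = R_PosInf;
  for (int j = 0, k = n - 1; j < n; k = j++) {
    double ax = X[k], ay = Y[k], bx = X[j], by = Y[j];
    double vx = bx - ax, vy = by - ay;
    double L2 = vx * vx + vy * vy;
    double t = L2 > 0 ? ((x - ax) * vx + (y - ay) * vy) / L2 : 0.0;
    t = t < 0 ? 0 : (t > 1 ? 1 : t);
    double dx = x - (ax + t * vx), dy = y - (ay + t * vy);
    double d = dx * dx + dy * dy;
    if (d < best) best = d;
  }
  return std::sqrt(best);
}

static double poly_gap(const Poly& a, const Poly& b) {
  for (size_t i = 0; i < a.x.size(); ++i)
    if (point_in(b.x, b.y, a.x[i], a.y[i])) return 0.0;
  for (size_t i = 0; i < b.x.size(); ++i)
    if (point_in(a.x, a.y, b.x[i], b.y[i])) return 0.0;
  double best = R_PosInf;
  for (size_t i = 0; i < a.x.size(); ++i) {
    double d = dist_boundary(b.x, b.y, a.x[i], a.y[i]);
    if (d < best) best = d;
  }
  for (size_t i = 0; i < b.x.size(); ++i) {
    double d = dist_boundary(a.x, a.y, b.x[i], b.y[i]);
    if (d < best) best = d;
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
List cpp_pack_relax(List templates, NumericVector rad, NumericMatrix epi,
                    NumericMatrix ctrs0, double min_gap,
                    double start_scale = 0.65, int max_steps = 600) {
  const int n = templates.size();
  std::vector<NumericMatrix> tm;
  for (int i = 0; i < n; ++i) tm.push_back(as<NumericMatrix>(templates[i]));
  std::vector<double> ex(epi.nrow()), ey(epi.nrow());
  for (int i = 0; i < epi.nrow(); ++i) { ex[i] = epi(i, 0); ey[i] = epi(i, 1); }
  double ecx = 0, ecy = 0;
  for (int i = 0; i < epi.nrow(); ++i) { ecx += ex[i]; ecy += ey[i]; }
  ecx /= epi.nrow(); ecy /= epi.nrow();

  std::vector<double> cx(n), cy(n), rot(n, 0.0);
  for (int i = 0; i < n; ++i) { cx[i] = ctrs0(i, 0); cy[i] = ctrs0(i, 1); }
  std::vector<Poly> P(n);
  const double tgt = min_gap * 1.02, tgt_b = min_gap / 2 * 1.02;

  double scale = start_scale;
  bool ok_all = true;
  while (true) {
    scale = std::min(1.0, scale * (scale < 0.9 ? 1.03 : 1.015));
    for (int i = 0; i < n; ++i) fill_poly(tm[i], scale, rot[i], cx[i], cy[i], P[i]);
    bool stage_ok = false;
    double best_worst = R_PosInf; int best_step = 0;
    for (int step = 0; step < max_steps; ++step) {
      double worst = 0.0; int worst_i = -1;
      // pairwise separation (sequential)
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = cx[j] - cx[i], dy = cy[j] - cy[i];
          double L = std::sqrt(dx * dx + dy * dy);
          if (L - (rad[i] + rad[j]) * scale >= tgt) continue;
          double g = poly_gap(P[i], P[j]);
          if (g < tgt) {
            double ux = L > 1e-9 ? dx / L : 1.0, uy = L > 1e-9 ? dy / L : 0.0;
            double push = (tgt - g) / 2;
            cx[i] -= ux * push; cy[i] -= uy * push;
            cx[j] += ux * push; cy[j] += uy * push;
            fill_poly(tm[i], scale, rot[i], cx[i], cy[i], P[i]);
            fill_poly(tm[j], scale, rot[j], cx[j], cy[j], P[j]);
            if (min_gap - g > worst) { worst = min_gap - g; worst_i = i; }
          }
        }
      // boundary containment
      for (int i = 0; i < n; ++i) {
        bool all_in = true;
        double clear = R_PosInf;
        for (size_t q = 0; q < P[i].x.size(); ++q) {
          if (!point_in(ex, ey, P[i].x[q], P[i].y[q])) { all_in = false; }
          double d = dist_boundary(ex, ey, P[i].x[q], P[i].y[q]);
          if (d < clear) clear = d;
        }
        if (!all_in || clear < tgt_b) {
          double pull = !all_in ? clear + tgt_b : tgt_b - clear;
          double dx = ecx - cx[i], dy = ecy - cy[i];
          double L = std::sqrt(dx * dx + dy * dy);
          if (L > 1e-9) {
            double mv = std::min(pull, L);
            cx[i] += dx / L * mv; cy[i] += dy / L * mv;
            fill_poly(tm[i], scale, rot[i], cx[i], cy[i], P[i]);
          }
          if (!all_in || clear < min_gap / 2) {
            if (worst < 1.0) { worst = 1.0; worst_i = i; }
          }
        }
      }
      if (worst <= 0.0) { stage_ok = true; break; }
      if (worst < best_worst - 1e-6) { best_worst = worst; best_step = step; }
      else if (step - best_step > 100) break;   // stalled stage
      // jammed shape: try template rotations, keep the best
      if (worst_i >= 0 && (step + 1) % 40 == 0) {
        double best_rot = rot[worst_i], best_score = -R_PosInf;
        Poly cand;
        for (double dr : {-30.0, -15.0, 15.0, 30.0}) {
          double r = rot[worst_i] + dr;
          fill_poly(tm[worst_i], scale, r, cx[worst_i], cy[worst_i], cand);
          double sc = R_PosInf;
          bool all_in = true;
          for (size_t q = 0; q < cand.x.size(); ++q)
            if (!point_in(ex, ey, cand.x[q], cand.y[q])) { all_in = false; break; }
          if (!all_in) continue;
          for (int j = 0; j < n; ++j) {
            if (j == worst_i) continue;
            double d = poly_gap(cand, P[j]);
            if (d < sc) sc = d;
          }
          if (sc > best_score) { best_score = sc; best_rot = r; }
        }
        // also score the current orientation
        {
          double sc = R_PosInf;
          for (int j = 0; j < n; ++j) {
            if (j == worst_i) continue;
            double d = poly_gap(P[worst_i], P[j]);
            if (d < sc) sc = d;
          }
          if (sc >= best_score) best_rot = rot[worst_i];
        }
        if (best_rot != rot[worst_i]) {
          rot[worst_i] = best_rot;
          fill_poly(tm[worst_i], scale, rot[worst_i], cx[worst_i], cy[worst_i],
                    P[worst_i]);
        }
      }
    }
    if (!stage_ok) { ok_all = false; break; }
    if (scale >= 1.0) break;
  }
  NumericMatrix ctrs(n, 2);
  NumericVector rots(n);
  for (int i = 0; i < n; ++i) { ctrs(i, 0) = cx[i]; ctrs(i, 1) = cy[i]; rots[i] = rot[i]; }
  return List::create(_["ok"] = ok_all, _["ctrs"] = ctrs, _["rot"] = rots,
                      _["scale"] = scale);
}
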
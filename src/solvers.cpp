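// Computational kernels: preconditioned conjugate-gradient solver for the
// rectilinear finite-volume current-conservation problem, trilinear
// interpolation on rectilinear grids, and implicit-Euler cable solvers for
// the myelinated-axon membrane models.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Structured-grid PCG
//
// Unknowns live at voxel centers of an nx*ny*nz rectilinear grid.
// gx (dims (nx-1, ny, nz)), gy, gz hold internal-face conductances (S);
// diag_add holds per-voxel extra diagonal terms (Dirichlet couplings, S);
// b is the source vector (A). Solves A v = b with Jacobi preconditioning.
// ---------------------------------------------------------------------------

static inline int IDX(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// diag_extra holds only the non-face diagonal terms (Dirichlet
// couplings); the face loops below account for the face contributions.
static void apply_A(const std::vector<double>& v, std::vector<double>& out,
                    int nx, int ny, int nz,
                    const double* gx, const double* gy, const double* gz,
                    const double* diag_extra) {
  const int n = nx * ny * nz;
  for (int q = 0; q < n; ++q) out[q] = diag_extra[q] * v[q];
  // x faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double g = gx[i + (nx - 1) * (j + ny * k)];
        if (g == 0.0) continue;
        int a = IDX(i, j, k, nx, ny), bI = IDX(i + 1, j, k, nx, ny);
        double f = g * (v[a] - v[bI]);
        out[a] += f; out[bI] -= f;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i) {
        double g = gy[i + nx * (j + (ny - 1) * k)];
        if (g == 0.0) continue;
        int a = IDX(i, j, k, nx, ny), bI = IDX(i, j + 1, k, nx, ny);
        double f = g * (v[a] - v[bI]);
        out[a] += f; out[bI] -= f;
      }
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double g = gz[i + nx * (j + ny * k)];
        if (g == 0.0) continue;
        int a = IDX(i, j, k, nx, ny), bI = IDX(i, j, k + 1, nx, ny);
        double f = g * (v[a] - v[bI]);
        out[a] += f; out[bI] -= f;
      }
}

// [[Rcpp::export]]
List pcg_structured(int nx, int ny, int nz,
                    NumericVector gx, NumericVector gy, NumericVector gz,
                    NumericVector diag_add, NumericVector b,
                    double tol = 1e-8, int maxit = 20000) {
  const int n = nx * ny * nz;
  // assemble the diagonal: sum of incident face conductances + diag_add
  std::vector<double> diag(diag_add.begin(), diag_add.end());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double g = gx[i + (nx - 1) * (j + ny * k)];
        diag[IDX(i, j, k, nx, ny)] += g;
        diag[IDX(i + 1, j, k, nx, ny)] += g;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i) {
        double g = gy[i + nx * (j + (ny - 1) * k)];
        diag[IDX(i, j, k, nx, ny)] += g;
        diag[IDX(i, j + 1, k, nx, ny)] += g;
      }
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double g = gz[i + nx * (j + ny * k)];
        diag[IDX(i, j, k, nx, ny)] += g;
        diag[IDX(i, j, k + 1, nx, ny)] += g;
      }
  std::vector<double> bb(b.begin(), b.end());
  std::vector<double> dextra(diag_add.begin(), diag_add.end());
  for (int q = 0; q < n; ++q)
    if (diag[q] <= 0.0) { diag[q] = 1.0; dextra[q] = 1.0; bb[q] = 0.0; }

  std::vector<double> v(n, 0.0), r(bb), z(n), p(n), Ap(n);
  double bnorm = 0.0;
  for (int q = 0; q < n; ++q) bnorm += bb[q] * bb[q];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["v"] = NumericVector(n), _["iter"] = 0,
                        _["relres"] = 0.0);
  double rz = 0.0;
  for (int q = 0; q < n; ++q) { z[q] = r[q] / diag[q]; rz += r[q] * z[q]; }
  p = z;
  double relres = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    apply_A(p, Ap, nx, ny, nz, gx.begin(), gy.begin(), gz.begin(),
            dextra.data());
    double pAp = 0.0;
    for (int q = 0; q < n; ++q) pAp += p[q] * Ap[q];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int q = 0; q < n; ++q) {
      v[q] += alpha * p[q];
      r[q] -= alpha * Ap[q];
      rnorm += r[q] * r[q];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres < tol) { ++it; break; }
    double rz_new = 0.0;
    for (int q = 0; q < n; ++q) { z[q] = r[q] / diag[q]; rz_new += r[q] * z[q]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int q = 0; q < n; ++q) p[q] = z[q] + beta * p[q];
  }
  return List::create(_["v"] = NumericVector(v.begin(), v.end()),
                      _["iter"] = it, _["relres"] = relres);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation on a rectilinear grid (cell-center coordinates).
// outside: 0 = NA (caller errors), 1 = zero, 2 = clamp to nearest.
// ---------------------------------------------------------------------------

static inline void locate(const NumericVector& c, double x, int& i0, double& w) {
  const int n = c.size();
  if (x <= c[0]) { i0 = 0; w = 0.0; return; }
  if (x >= c[n - 1]) { i0 = n - 2 >= 0 ? n - 2 : 0; w = 1.0; return; }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (c[mid] <= x) lo = mid; else hi = mid; }
  i0 = lo;
  w = (x - c[lo]) / (c[hi] - c[lo]);
}

// [[Rcpp::export]]
NumericVector trilinear_interp(NumericVector xc, NumericVector yc,
                               NumericVector zc, NumericVector field,
                               NumericMatrix pts,
                               double xlo, double xhi, double ylo, double yhi,
                               double zlo, double zhi, int outside = 0) {
  const int nx = xc.size(), ny = yc.size();
  const int m = pts.nrow();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    bool in = (x >= xlo && x <= xhi && y >= ylo && y <= yhi &&
               z >= zlo && z <= zhi);
    if (!in) {
      if (outside == 1) { out[q] = 0.0; continue; }
      if (outside == 0) { out[q] = NA_REAL; continue; }
      x = std::min(std::max(x, xlo), xhi);
      y = std::min(std::max(y, ylo), yhi);
      z = std::min(std::max(z, zlo), zhi);
    }
    int i0, j0, k0; double wx, wy, wz;
    locate(xc, x, i0, wx); locate(yc, y, j0, wy); locate(zc, z, k0, wz);
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
          if (w == 0.0) continue;
          acc += w * field[IDX(i0 + di, j0 + dj, k0 + dk, nx, ny)];
        }
    out[q] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// MRG nodal channel kinetics (36 C, Q10 factors folded into the rates).
// Gate update by Rush-Larsen with rate lookup tables.
// ---------------------------------------------------------------------------

struct RateTab {
  static const int N = 2801;
  double vmin = -180.0, dv = 0.1;
  std::vector<double> minf, mtau, hinf, htau, pinf, ptau, sinf, stau;
  RateTab() {
    minf.resize(N); mtau.resize(N); hinf.resize(N); htau.resize(N);
    pinf.resize(N); ptau.resize(N); sinf.resize(N); stau.resize(N);
    for (int i = 0; i < N; ++i) {
      double v = vmin + i * dv;
      double am = vtrap(6.57, v + 20.4, 10.3);
      double bm = vtrap(0.304, -(v + 25.7), 9.16);
      double ah = vtrap(0.34, -(v + 114.0), 11.0);
      double bh = 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
      double ap = vtrap(0.0353, v + 27.0, 10.2);
      double bp = vtrap(0.000883, -(v + 34.0), 10.0);
      double as = 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
      double bs = 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
      set(minf, mtau, i, am, bm);
      set(hinf, htau, i, ah, bh);
      set(pinf, ptau, i, ap, bp);
      set(sinf, stau, i, as, bs);
    }
  }
  static double vtrap(double a, double x, double b) {
    // a * x / (1 - exp(-x/b)) with the removable singularity handled
    double r = x / b;
    if (std::fabs(r) < 1e-6) return a * b * (1.0 + r / 2.0);
    return a * x / (1.0 - std::exp(-r));
  }
  static void set(std::vector<double>& xinf, std::vector<double>& xtau, int i,
                  double a, double b) {
    double s = a + b;
    if (s < 1e-12) s = 1e-12;
    xinf[i] = a / s; xtau[i] = 1.0 / s;
  }
  inline void look(double v, const std::vector<double>& tab, double& out) const {
    double f = (v - vmin) / dv;
    if (f <= 0) { out = tab[0]; return; }
    if (f >= N - 1) { out = tab[N - 1]; return; }
    int i = (int)f; double w = f - i;
    out = tab[i] * (1 - w) + tab[i + 1] * w;
  }
};

static RateTab& rate_tab() {
  static RateTab tab;
  return tab;
}

// ---------------------------------------------------------------------------
// Reduced single-cable solver: active nodes + lumped passive myelinated
// internode compartments. Implicit (backward Euler) voltage update with
// Rush-Larsen gates; extracellular drive enters through the axial terms.
// Units: mV, ms, uF, mS, uA.
// Returns 1 if an action potential (upward 0 mV crossing) is seen at both
// terminal compartments within the window, else 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cable_sim_reduced(NumericVector cm, NumericVector gpas, NumericVector epas,
                      IntegerVector is_node,
                      NumericVector gnaf, NumericVector gnap,
                      NumericVector gks, NumericVector gl,
                      NumericVector gax,
                      NumericVector ve_mV, double amp,
                      double dt, int n_steps, int pulse_steps,
                      double v_rest, double e_na, double e_k, double e_l) {
  const int n = cm.size();
  RateTab& RT = rate_tab();
  std::vector<double> V(n, v_rest), m(n), h(n), p(n), s(n);
  for (int i = 0; i < n; ++i) {
    if (!is_node[i]) continue;
    double mi, hi, pi, si, dum;
    RT.look(v_rest, RT.minf, mi); RT.look(v_rest, RT.hinf, hi);
    RT.look(v_rest, RT.pinf, pi); RT.look(v_rest, RT.sinf, si);
    (void)dum;
    m[i] = mi; h[i] = hi; p[i] = pi; s[i] = si;
  }
  std::vector<double> a(n), bdia(n), c(n), rhs(n), cp(n), dp(n);
  bool sp_first = false, sp_last = false;
  double prev_first = V[0], prev_last = V[n - 1];
  int decay_run = 0;
  double prev_max = v_rest;
  for (int t = 0; t < n_steps; ++t) {
    double drive = (t < pulse_steps) ? amp : 0.0;
    // gates from current voltage (Rush-Larsen)
    for (int i = 0; i < n; ++i) {
      if (!is_node[i]) continue;
      double xinf, xtau;
      RT.look(V[i], RT.minf, xinf); RT.look(V[i], RT.mtau, xtau);
      m[i] = xinf + (m[i] - xinf) * std::exp(-dt / xtau);
      RT.look(V[i], RT.hinf, xinf); RT.look(V[i], RT.htau, xtau);
      h[i] = xinf + (h[i] - xinf) * std::exp(-dt / xtau);
      RT.look(V[i], RT.pinf, xinf); RT.look(V[i], RT.ptau, xtau);
      p[i] = xinf + (p[i] - xinf) * std::exp(-dt / xtau);
      RT.look(V[i], RT.sinf, xinf); RT.look(V[i], RT.stau, xtau);
      s[i] = xinf + (s[i] - xinf) * std::exp(-dt / xtau);
    }
    // assemble tridiagonal system
    for (int i = 0; i < n; ++i) {
      double gsum = 0.0, isrc = 0.0;
      if (i > 0) {
        gsum += gax[i - 1];
        isrc += gax[i - 1] * (ve_mV[i - 1] - ve_mV[i]) * drive;
      }
      if (i < n - 1) {
        gsum += gax[i];
        isrc += gax[i] * (ve_mV[i + 1] - ve_mV[i]) * drive;
      }
      double glin, erev_term;
      if (is_node[i]) {
        double gna = gnaf[i] * m[i] * m[i] * m[i] * h[i] + gnap[i] * p[i] * p[i] * p[i];
        double gk = gks[i] * s[i];
        glin = gna + gk + gl[i];
        erev_term = gna * e_na + gk * e_k + gl[i] * e_l;
      } else {
        glin = gpas[i];
        erev_term = gpas[i] * epas[i];
      }
      bdia[i] = cm[i] / dt + glin + gsum;
      a[i] = (i > 0) ? -gax[i - 1] : 0.0;
      c[i] = (i < n - 1) ? -gax[i] : 0.0;
      rhs[i] = cm[i] / dt * V[i] + erev_term + isrc;
    }
    // Thomas solve
    cp[0] = c[0] / bdia[0]; dp[0] = rhs[0] / bdia[0];
    for (int i = 1; i < n; ++i) {
      double mlt = bdia[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / mlt;
      dp[i] = (rhs[i] - a[i] * dp[i - 1]) / mlt;
    }
    V[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];
    // spike detection at the terminal compartments
    if (!sp_first && prev_first < 0.0 && V[0] >= 0.0) sp_first = true;
    if (!sp_last && prev_last < 0.0 && V[n - 1] >= 0.0) sp_last = true;
    prev_first = V[0]; prev_last = V[n - 1];
    if (sp_first && sp_last) return 1;
    if (!R_FINITE(V[0]) || !R_FINITE(V[n - 1]))
      stop("membrane solver became non-finite; reduce the time step");
    // early no-spike exit: post-pulse, everything subthreshold and decaying
    if (t >= pulse_steps) {
      double vmax = V[0];
      for (int i = 1; i < n; ++i) if (V[i] > vmax) vmax = V[i];
      if (vmax < v_rest + 20.0 && vmax <= prev_max + 1e-9) ++decay_run;
      else decay_run = 0;
      prev_max = vmax;
      if (decay_run > 150 && !sp_first && !sp_last) return 0;
    }
  }
  return (sp_first && sp_last) ? 1 : 0;
}

// ---------------------------------------------------------------------------
// Full MRG double-cable solver: explicit periaxonal space under the myelin
// (MYSA/FLUT/STIN sections). Unknowns interleaved [Vm_0, Vp_0, Vm_1, ...];
// the banded (bandwidth 3) system is factorized each step.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cable_sim_mrg(NumericVector cm, NumericVector cmy,
                  NumericVector gmy, NumericVector gpas, NumericVector epas,
                  IntegerVector is_node,
                  NumericVector gnaf, NumericVector gnap,
                  NumericVector gks, NumericVector gl,
                  NumericVector gax, NumericVector gpx,
                  NumericVector ve_mV, double amp,
                  double dt, int n_steps, int pulse_steps,
                  double v_rest, double e_na, double e_k, double e_l) {
  const int n = cm.size();
  const int N = 2 * n;
  const int kl = 3, ku = 3, ld = 2 * kl + ku + 1; // LAPACK-style band storage
  RateTab& RT = rate_tab();
  std::vector<double> Vm(n, v_rest), Vp(n, 0.0), m(n), h(n), p(n), s(n);
  for (int i = 0; i < n; ++i) {
    if (!is_node[i]) continue;
    double x;
    RT.look(v_rest, RT.minf, x); m[i] = x;
    RT.look(v_rest, RT.hinf, x); h[i] = x;
    RT.look(v_rest, RT.pinf, x); p[i] = x;
    RT.look(v_rest, RT.sinf, x); s[i] = x;
  }
  std::vector<double> band(ld * N), rhs(N);
  std::vector<int> piv(N);
  bool sp_first = false, sp_last = false;
  double prev_first = Vm[0], prev_last = Vm[n - 1];
  int decay_run = 0; double prev_max = v_rest;

  auto BAND = [&](int r, int cIdx) -> double& {
    // element (r, c) with kl <= r - c + kl + ku <= ...: storage row = kl + ku + r - c
    return band[(kl + ku + r - cIdx) + ld * cIdx];
  };

  for (int t = 0; t < n_steps; ++t) {
    double drive = (t < pulse_steps) ? amp : 0.0;
    for (int i = 0; i < n; ++i) {
      if (!is_node[i]) continue;
      double xinf, xtau;
      RT.look(Vm[i], RT.minf, xinf); RT.look(Vm[i], RT.mtau, xtau);
      m[i] = xinf + (m[i] - xinf) * std::exp(-dt / xtau);
      RT.look(Vm[i], RT.hinf, xinf); RT.look(Vm[i], RT.htau, xtau);
      h[i] = xinf + (h[i] - xinf) * std::exp(-dt / xtau);
      RT.look(Vm[i], RT.pinf, xinf); RT.look(Vm[i], RT.ptau, xtau);
      p[i] = xinf + (p[i] - xinf) * std::exp(-dt / xtau);
      RT.look(Vm[i], RT.sinf, xinf); RT.look(Vm[i], RT.stau, xtau);
      s[i] = xinf + (s[i] - xinf) * std::exp(-dt / xtau);
    }
    std::fill(band.begin(), band.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double glin, erev;
      if (is_node[i]) {
        double gna = gnaf[i] * m[i] * m[i] * m[i] * h[i] + gnap[i] * p[i] * p[i] * p[i];
        double gk = gks[i] * s[i];
        glin = gna + gk + gl[i];
        erev = gna * e_na + gk * e_k + gl[i] * e_l;
      } else {
        glin = gpas[i];
        erev = gpas[i] * epas[i];
      }
      int rm = 2 * i, rp = 2 * i + 1;
      double ga_l = (i > 0) ? gax[i - 1] : 0.0;
      double ga_r = (i < n - 1) ? gax[i] : 0.0;
      double gp_l = (i > 0) ? gpx[i - 1] : 0.0;
      double gp_r = (i < n - 1) ? gpx[i] : 0.0;
      double gasum = ga_l + ga_r, gpsum = gp_l + gp_r;
      double isrc_a = ga_l * (ve_mV[i - 1 >= 0 ? i - 1 : 0] - ve_mV[i]) * drive +
                      ga_r * (ve_mV[i + 1 < n ? i + 1 : i] - ve_mV[i]) * drive;
      double isrc_p = gp_l * (ve_mV[i - 1 >= 0 ? i - 1 : 0] - ve_mV[i]) * drive +
                      gp_r * (ve_mV[i + 1 < n ? i + 1 : i] - ve_mV[i]) * drive;
      // axolemma row
      BAND(rm, rm) += cm[i] / dt + glin + gasum;
      BAND(rm, rp) += gasum;
      if (i > 0) { BAND(rm, rm - 2) -= ga_l; BAND(rm, rm - 1) -= ga_l; }
      if (i < n - 1) { BAND(rm, rm + 2) -= ga_r; BAND(rm, rm + 3) -= ga_r; }
      rhs[rm] = cm[i] / dt * Vm[i] + erev + isrc_a;
      // periaxonal row
      BAND(rp, rp) += cmy[i] / dt + gmy[i] + gasum + gpsum;
      BAND(rp, rm) += gasum;
      if (i > 0) {
        BAND(rp, rp - 3) -= ga_l;
        BAND(rp, rp - 2) -= (ga_l + gp_l);
      }
      if (i < n - 1) {
        BAND(rp, rp + 1) -= ga_r;
        BAND(rp, rp + 2) -= (ga_r + gp_r);
      }
      rhs[rp] = cmy[i] / dt * Vp[i] + isrc_a + isrc_p;
    }
    // banded LU with partial pivoting (bandwidth may grow to kl+ku)
    for (int ccol = 0; ccol < N; ++ccol) {
      int rmax = std::min(N - 1, ccol + kl);
      int pivot = ccol;
      double amax = std::fabs(BAND(ccol, ccol));
      for (int r = ccol + 1; r <= rmax; ++r) {
        double av = std::fabs(BAND(r, ccol));
        if (av > amax) { amax = av; pivot = r; }
      }
      piv[ccol] = pivot;
      if (amax == 0.0) stop("singular cable system");
      int cend = std::min(N - 1, ccol + kl + ku);
      if (pivot != ccol) {
        for (int cc = ccol; cc <= cend; ++cc)
          std::swap(BAND(ccol, cc), BAND(pivot, cc));
        std::swap(rhs[ccol], rhs[pivot]);
      }
      double d = BAND(ccol, ccol);
      for (int r = ccol + 1; r <= rmax; ++r) {
        double f = BAND(r, ccol) / d;
        if (f == 0.0) continue;
        BAND(r, ccol) = 0.0;
        for (int cc = ccol + 1; cc <= cend; ++cc)
          BAND(r, cc) -= f * BAND(ccol, cc);
        rhs[r] -= f * rhs[ccol];
      }
    }
    for (int r = N - 1; r >= 0; --r) {
      double acc = rhs[r];
      int cend = std::min(N - 1, r + kl + ku);
      for (int cc = r + 1; cc <= cend; ++cc) acc -= BAND(r, cc) * (cc % 2 ? Vp[cc / 2] : Vm[cc / 2]);
      acc /= BAND(r, r);
      if (r % 2) Vp[r / 2] = acc; else Vm[r / 2] = acc;
    }
    if (!sp_first && prev_first < 0.0 && Vm[0] >= 0.0) sp_first = true;
    if (!sp_last && prev_last < 0.0 && Vm[n - 1] >= 0.0) sp_last = true;
    prev_first = Vm[0]; prev_last = Vm[n - 1];
    if (sp_first && sp_last) return 1;
    if (!R_FINITE(Vm[0]) || !R_FINITE(Vm[n - 1]))
      stop("membrane solver became non-finite; reduce the time step");
    if (t >= pulse_steps) {
      double vmax = Vm[0];
      for (int i = 1; i < n; ++i) if (Vm[i] > vmax) vmax = Vm[i];
      if (vmax < v_rest + 20.0 && vmax <= prev_max + 1e-9) ++decay_run;
      else decay_run = 0;
      prev_max = vmax;
      if (decay_run > 150 && !sp_first && !sp_last) return 0;
    }
  }
  return (sp_first && sp_last) ? 1 : 0;
}
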
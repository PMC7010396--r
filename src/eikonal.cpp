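// Anisotropic eikonal solver on the (x, y, theta) chart of SO(3).
//
// The Riemannian approximation of the sub-Riemannian metric is
//   M_eps = C^2 * R diag(xi^2, 1, xi^2/eps^2) R^T
// and the eikonal equation  grad(W)' M_eps^{-1} grad(W) = 1  is discretized
// with adaptive anisotropic stencils: at each (x, theta) the index-space
// inverse metric D = S M1^{-1} S (S = diag(1/hx, 1/hy, 1/ht)) is decomposed
// by Selling's algorithm into  D = sum_k rho_k b_k b_k^T  with integer
// offsets b_k, giving the monotone upwind scheme
//   sum_k rho_k max(0, u - a_k)^2 = C^2,   a_k = min(W(p+b_k), W(p-b_k)).
// The offsets automatically elongate along the cheap sub-Riemannian
// directions, which keeps the scheme accurate under strong anisotropy.
//
// Two drivers share the update: a label-correcting priority queue ("fast
// marching"; re-insertion handles residual acausality) and Gauss-Seidel
// sweeps. Both are polished by sweeps to the common fixed point, so the
// result is driver-independent and deterministic.
//
// Axes: x (latitude, non-periodic, index fastest), y and theta periodic.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double INF = 1e100;

struct Grid {
  int nx, ny, nt;
  double hx, hy, ht;
  std::vector<double> xs, ths;
};

static inline int wrap(int i, int n) { int r = i % n; return r < 0 ? r + n : r; }

static inline long idx3(int ix, int iy, int it, const Grid& g) {
  return (long)ix + (long)g.nx * ((long)iy + (long)g.ny * (long)it);
}

// unit-cost metric M1 at (x, theta)
static void metric33(double x, double th, double xi, double eps, double M[3][3]) {
  double R[3][3] = {
    { std::cos(th), 0.0, std::sin(th) },
    { -std::cos(x) * std::sin(th), std::sin(x), std::cos(x) * std::cos(th) },
    { 0.0, 1.0, 0.0 } };
  double D[3] = { xi * xi, 1.0, xi * xi / (eps * eps) };
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += R[i][k] * D[k] * R[j][k];
      M[i][j] = s;
    }
}

static void invert33(const double A[3][3], double Ai[3][3]) {
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
             - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
             + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  Ai[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  Ai[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
  Ai[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  Ai[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
  Ai[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  Ai[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
  Ai[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  Ai[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
  Ai[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
}

// Selling's decomposition of a 3D SPD matrix: D = sum_{k=1..6} rho_k b_k b_k'
struct Term { double rho; int b[3]; };

static bool selling3(const double D[3][3], Term out[6]) {
  long V[3][4] = { {1,0,0,-1}, {0,1,0,-1}, {0,0,1,-1} };
  auto quad = [&](int i, int j) {
    double s = 0.0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        s += (double)V[a][i] * D[a][b] * (double)V[b][j];
    return s;
  };
  for (int iter = 0; iter < 1000; ++iter) {
    bool done = true;
    for (int i = 0; i < 4 && done; ++i)
      for (int j = i + 1; j < 4 && done; ++j)
        if (quad(i, j) > 1e-12 * (std::fabs(quad(i, i)) + std::fabs(quad(j, j)))) {
          int k = 0, l = 0, seen = 0;
          for (int m = 0; m < 4; ++m) if (m != i && m != j) { (seen++ ? l : k) = m; }
          for (int a = 0; a < 3; ++a) {
            long vi = V[a][i];
            V[a][i] = -vi;
            V[a][k] += vi;
            V[a][l] += vi;
          }
          done = false;
        }
    if (done) {
      static const int pairs[6][2] = { {0,1},{0,2},{0,3},{1,2},{1,3},{2,3} };
      for (int p = 0; p < 6; ++p) {
        int i = pairs[p][0], j = pairs[p][1];
        int k = 0, l = 0, seen = 0;
        for (int m = 0; m < 4; ++m) if (m != i && m != j) { (seen++ ? l : k) = m; }
        out[p].rho = -quad(i, j);
        if (out[p].rho < 0.0) out[p].rho = 0.0;
        out[p].b[0] = (int)(V[1][k] * V[2][l] - V[2][k] * V[1][l]);
        out[p].b[1] = (int)(V[2][k] * V[0][l] - V[0][k] * V[2][l]);
        out[p].b[2] = (int)(V[0][k] * V[1][l] - V[1][k] * V[0][l]);
      }
      return true;
    }
  }
  return false;
}

struct Solver {
  Grid g;
  double xi, eps;
  std::vector<double> cost;        // nx * ny, theta-invariant
  std::vector<double> W;
  std::vector<Term> stencil;       // per (ix, it): 6 terms

  bool precompute() {
    stencil.assign((size_t)g.nx * g.nt * 6, Term());
    double M[3][3], Mi[3][3], D[3][3];
    for (int ix = 0; ix < g.nx; ++ix)
      for (int it = 0; it < g.nt; ++it) {
        metric33(g.xs[ix], g.ths[it], xi, eps, M);
        invert33(M, Mi);
        double s[3] = { 1.0 / g.hx, 1.0 / g.hy, 1.0 / g.ht };
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            D[a][b] = s[a] * Mi[a][b] * s[b];
        if (!selling3(D, &stencil[((size_t)ix * g.nt + it) * 6])) return false;
      }
    return true;
  }

  // upwind neighbor data along offset b: first-order value a, and the
  // second-order corrected pair (a2, weight factor 9/4) when the ray is
  // monotone (standard high-accuracy fast-marching correction)
  inline void neighbor_dir(int ix, int iy, int it, const int b[3], int sgn,
                           double& a, double& a2) {
    a = INF; a2 = INF;
    int jx = ix + sgn * b[0];
    if (jx < 0 || jx >= g.nx) return;
    double w1 = W[idx3(jx, wrap(iy + sgn * b[1], g.ny),
                       wrap(it + sgn * b[2], g.nt), g)];
    if (w1 >= INF) return;
    a = w1;
    int kx = ix + 2 * sgn * b[0];
    if (kx < 0 || kx >= g.nx) return;
    double w2 = W[idx3(kx, wrap(iy + 2 * sgn * b[1], g.ny),
                       wrap(it + 2 * sgn * b[2], g.nt), g)];
    if (w2 < w1) a2 = (4.0 * w1 - w2) / 3.0;
  }

  double update_value(int ix, int iy, int it, bool second_order) {
    const Term* st = &stencil[((size_t)ix * g.nt + it) * 6];
    double c = cost[(size_t)ix + (size_t)g.nx * iy];
    double c2 = c * c;
    double rho[6], a[6];
    int n = 0;
    for (int k = 0; k < 6; ++k) {
      if (st[k].rho <= 0.0) continue;
      double ap, a2p, am, a2m;
      neighbor_dir(ix, iy, it, st[k].b, +1, ap, a2p);
      neighbor_dir(ix, iy, it, st[k].b, -1, am, a2m);
      double a1 = std::min(ap, am);
      if (a1 >= INF) continue;
      double rk = st[k].rho, ak = a1;
      if (second_order) {
        double a2 = (ap <= am) ? a2p : a2m;
        if (a2 < INF) { rk *= 2.25; ak = a2; }
      }
      rho[n] = rk; a[n] = ak; ++n;
    }
    if (n == 0) return INF;
    // insertion sort by a
    for (int i = 1; i < n; ++i) {
      double ra = rho[i], aa = a[i];
      int j = i - 1;
      while (j >= 0 && a[j] > aa) { a[j + 1] = a[j]; rho[j + 1] = rho[j]; --j; }
      a[j + 1] = aa; rho[j + 1] = ra;
    }
    // solve sum_{k<=m} rho_k (u - a_k)^2 = c2 with growing active set
    double A = 0.0, B = 0.0, E = 0.0, u = INF;
    for (int m = 0; m < n; ++m) {
      A += rho[m]; B += rho[m] * a[m]; E += rho[m] * a[m] * a[m];
      double disc = B * B - A * (E - c2);
      if (disc < 0.0) continue;
      double cand = (B + std::sqrt(disc)) / A;
      if (cand < a[m]) continue;                 // inconsistent active set
      if (m + 1 < n && cand > a[m + 1]) continue; // more terms must enter
      u = cand;
      break;
    }
    return u;
  }

  void init_seed(int sx, int sy, int st) {
    W.assign((size_t)g.nx * g.ny * g.nt, INF);
    W[idx3(sx, sy, st, g)] = 0.0;
    double M[3][3];
    for (int dx = -2; dx <= 2; ++dx)
      for (int dy = -2; dy <= 2; ++dy)
        for (int dt = -2; dt <= 2; ++dt) {
          if (!dx && !dy && !dt) continue;
          int jx = sx + dx;
          if (jx < 0 || jx >= g.nx) continue;
          int jy = wrap(sy + dy, g.ny), jt = wrap(st + dt, g.nt);
          double xm = 0.5 * (g.xs[sx] + g.xs[jx]);
          double tm = g.ths[st] + 0.5 * dt * g.ht;
          metric33(xm, tm, xi, eps, M);
          double e[3] = { dx * g.hx, dy * g.hy, dt * g.ht };
          double q = 0.0;
          for (int aa = 0; aa < 3; ++aa)
            for (int bb = 0; bb < 3; ++bb)
              q += e[aa] * M[aa][bb] * e[bb];
          double c = 0.5 * (cost[(size_t)sx + (size_t)g.nx * sy]
                            + cost[(size_t)jx + (size_t)g.nx * jy]);
          W[idx3(jx, jy, jt, g)] = c * std::sqrt(q);
        }
  }

  void run_queue(long target, double tol) {
    typedef std::pair<double, long> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    for (long i = 0; i < (long)W.size(); ++i)
      if (W[i] < INF) pq.push(QE(W[i], i));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      long i = top.second;
      if (top.first > W[i] * (1.0 + 1e-12) + 1e-14) continue;
      if (target >= 0 && top.first > W[target]) break;
      int ix = (int)(i % g.nx);
      int iy = (int)((i / g.nx) % g.ny);
      int it = (int)(i / ((long)g.nx * g.ny));
      const Term* st = &stencil[((size_t)ix * g.nt + it) * 6];
      for (int k = 0; k < 6; ++k) {
        if (st[k].rho <= 0.0) continue;
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int jx = ix + sgn * st[k].b[0];
          if (jx < 0 || jx >= g.nx) continue;
          int jy = wrap(iy + sgn * st[k].b[1], g.ny);
          int jt = wrap(it + sgn * st[k].b[2], g.nt);
          long j = idx3(jx, jy, jt, g);
          double f = update_value(jx, jy, jt, false);
          if (f < W[j] - tol) { W[j] = f; pq.push(QE(f, j)); }
        }
      }
    }
  }

  // Gauss-Seidel sweeps in 8 alternating orders; returns last max change
  double run_sweeps(double tol, int max_sweeps, bool second_order) {
    double maxch = INF;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      maxch = 0.0;
      int dir = sweep % 8;
      int sx = (dir & 1) ? 1 : -1, sy = (dir & 2) ? 1 : -1, st = (dir & 4) ? 1 : -1;
      for (int ii = 0; ii < g.nx; ++ii) {
        int ix = sx > 0 ? ii : g.nx - 1 - ii;
        for (int jj = 0; jj < g.ny; ++jj) {
          int iy = sy > 0 ? jj : g.ny - 1 - jj;
          for (int kk = 0; kk < g.nt; ++kk) {
            int it = st > 0 ? kk : g.nt - 1 - kk;
            long i = idx3(ix, iy, it, g);
            if (W[i] == 0.0) continue;
            double f = update_value(ix, iy, it, second_order);
            if (f < W[i] - 1e-300) {
              double ch = W[i] - f;
              if (ch < INF) maxch = std::max(maxch, ch);
              else maxch = INF;
              W[i] = f;
            }
          }
        }
      }
      if (sweep >= 8 && maxch < tol) break;
      Rcpp::checkUserInterrupt();
    }
    return maxch;
  }
};

// [[Rcpp::export]]
NumericVector solve_eikonal_cpp(NumericMatrix cost_xy,
                                NumericVector xnodes, NumericVector ynodes,
                                NumericVector tnodes,
                                double xi, double eps,
                                IntegerVector seed_idx0,
                                int scheme, double tol, int max_sweeps,
                                double target_idx0, int order) {
  Solver s;
  s.g.nx = xnodes.size(); s.g.ny = ynodes.size(); s.g.nt = tnodes.size();
  s.g.hx = xnodes[1] - xnodes[0];
  s.g.hy = ynodes[1] - ynodes[0];
  s.g.ht = tnodes[1] - tnodes[0];
  s.g.xs.assign(xnodes.begin(), xnodes.end());
  s.g.ths.assign(tnodes.begin(), tnodes.end());
  s.xi = xi; s.eps = eps;
  s.cost.assign(cost_xy.begin(), cost_xy.end());
  if (!s.precompute()) stop("Selling decomposition of the metric failed");
  s.init_seed(seed_idx0[0], seed_idx0[1], seed_idx0[2]);
  long target = (long)target_idx0;
  if (scheme == 0) {
    s.run_queue(target, tol);
    if (target < 0) {
      s.run_sweeps(tol, max_sweeps, false);   // fixed point of the 1st-order scheme
      if (order >= 2) s.run_sweeps(tol, max_sweeps, true);
    }
  } else {
    s.run_sweeps(tol, max_sweeps, false);
    if (order >= 2) s.run_sweeps(tol, max_sweeps, true);
  }
  NumericVector out(s.W.begin(), s.W.end());
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] >= INF) out[i] = R_PosInf;
  return out;
}

// ---------------------------------------------------------------------------
// Tricubic (Catmull-Rom) interpolation of a chart field with gradient.

static inline void cr_weights(double u, double* w, double* dw) {
  w[0] = 0.5 * (-u + 2.0 * u * u - u * u * u);
  w[1] = 0.5 * (2.0 - 5.0 * u * u + 3.0 * u * u * u);
  w[2] = 0.5 * (u + 4.0 * u * u - 3.0 * u * u * u);
  w[3] = 0.5 * (-u * u + u * u * u);
  dw[0] = 0.5 * (-1.0 + 4.0 * u - 3.0 * u * u);
  dw[1] = 0.5 * (-10.0 * u + 9.0 * u * u);
  dw[2] = 0.5 * (1.0 + 8.0 * u - 9.0 * u * u);
  dw[3] = 0.5 * (-2.0 * u + 3.0 * u * u);
}

// [[Rcpp::export]]
List interp_tricubic_cpp(NumericVector W, IntegerVector dims,
                         double x0, double hx, double y0, double hy,
                         double t0, double ht, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nt = dims[2];
  int n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, 3);
  for (int p = 0; p < n; ++p) {
    double fx = (pts(p, 0) - x0) / hx;
    double fy = (pts(p, 1) - y0) / hy;
    double ft = (pts(p, 2) - t0) / ht;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy), it = (int)std::floor(ft);
    if (ix < 1) ix = 1;
    if (ix > nx - 3) ix = nx - 3;
    double ux = fx - ix, uy = fy - iy, ut = ft - it;
    double wx[4], dwx[4], wy[4], dwy[4], wt[4], dwt[4];
    cr_weights(ux, wx, dwx);
    cr_weights(uy, wy, dwy);
    cr_weights(ut, wt, dwt);
    double v = 0.0, gx = 0.0, gy = 0.0, gt = 0.0;
    bool bad = false;
    for (int a = 0; a < 4 && !bad; ++a) {
      int jx = ix + a - 1;
      if (jx < 0) jx = 0;
      if (jx > nx - 1) jx = nx - 1;
      for (int b = 0; b < 4 && !bad; ++b) {
        int jy = wrap(iy + b - 1, ny);
        for (int cI = 0; cI < 4; ++cI) {
          int jt = wrap(it + cI - 1, nt);
          double wv = W[(long)jx + (long)nx * ((long)jy + (long)ny * jt)];
          if (!R_FINITE(wv)) { bad = true; break; }
          v  += wx[a] * wy[b] * wt[cI] * wv;
          gx += dwx[a] * wy[b] * wt[cI] * wv;
          gy += wx[a] * dwy[b] * wt[cI] * wv;
          gt += wx[a] * wy[b] * dwt[cI] * wv;
        }
      }
    }
    if (bad) {
      val[p] = R_PosInf;
      grad(p, 0) = grad(p, 1) = grad(p, 2) = NA_REAL;
    } else {
      val[p] = v;
      grad(p, 0) = gx / hx;
      grad(p, 1) = gy / hy;
      grad(p, 2) = gt / ht;
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad);
}
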
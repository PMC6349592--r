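// Low-level geometric kernels: ray casting, point-in-mesh parity tests,
// closest-point queries and tetrahedral point location. These are the hot
// paths of the SDF segmentation, background-grid tet meshing, semi-Lagrangian
// advection and particle tracking.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double TINY = 1e-14;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 sub(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 add(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 scl(const V3& a, double s) { return V3(a.x*s, a.y*s, a.z*s); }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }

static inline V3 getrow(const NumericMatrix& M, int i) {
  return V3(M(i, 0), M(i, 1), M(i, 2));
}

// Moeller-Trumbore; returns true on hit with barycentric-inside test,
// t unrestricted in sign. Inclusive boundaries (eps slack) so that rays
// through shared edges are still counted by at least one triangle.
static bool ray_tri(const V3& o, const V3& d, const V3& a, const V3& b, const V3& c,
                    double& t) {
  V3 e1 = sub(b, a), e2 = sub(c, a);
  V3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < TINY) return false;
  double inv = 1.0 / det;
  V3 s = sub(o, a);
  double u = dot(s, p) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return false;
  V3 q = cross(s, e1);
  double v = dot(d, q) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return false;
  t = dot(e2, q) * inv;
  return true;
}

// First valid hit for a fan of rays from one origin.
// exclude_face: 0-based face to skip (-1 = none). If filter_normals, hits on
// faces whose outward normal has positive dot with src_normal are discarded
// (the false-intersection rule of the shape diameter function).
// [[Rcpp::export]]
NumericVector cpp_ray_first_hits(NumericMatrix V, IntegerMatrix F,
                                 NumericVector origin, NumericMatrix dirs,
                                 int exclude_face, NumericVector src_normal,
                                 bool filter_normals, double t_min) {
  int nf = F.nrow(), nr = dirs.nrow();
  V3 o(origin[0], origin[1], origin[2]);
  V3 sn(src_normal[0], src_normal[1], src_normal[2]);
  NumericVector out(nr, NA_REAL);
  std::vector<V3> A(nf), B(nf), C(nf), N(nf);
  for (int f = 0; f < nf; ++f) {
    A[f] = getrow(V, F(f, 0) - 1); B[f] = getrow(V, F(f, 1) - 1);
    C[f] = getrow(V, F(f, 2) - 1);
    N[f] = cross(sub(B[f], A[f]), sub(C[f], A[f]));
  }
  for (int r = 0; r < nr; ++r) {
    V3 d = getrow(dirs, r);
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      if (f == exclude_face) continue;
      double t;
      if (!ray_tri(o, d, A[f], B[f], C[f], t)) continue;
      if (t <= t_min || t >= best) continue;
      if (filter_normals && dot(N[f], sn) > 0) continue;
      best = t;
    }
    if (std::isfinite(best)) out[r] = best;
  }
  return out;
}

// ---- 2-D bucket grid over triangles projected orthogonally to a ray
// direction; used by the parity point-in-mesh test.
struct TriGrid2D {
  V3 e1, e2, d;
  double x0, y0, hx, hy;
  int nx, ny;
  std::vector< std::vector<int> > cells;
  inline int cix(double u) const {
    int i = (int)std::floor((u - x0) / hx);
    return std::min(std::max(i, 0), nx - 1);
  }
  inline int ciy(double v) const {
    int i = (int)std::floor((v - y0) / hy);
    return std::min(std::max(i, 0), ny - 1);
  }
};

// Parity (crossing-number) inside test along direction dir. Points lying on
// the surface (a hit with |t| < on_tol) count as inside.
// [[Rcpp::export]]
IntegerVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P,
                                 NumericVector dir, double on_tol) {
  int nf = F.nrow(), np = P.nrow();
  V3 d(dir[0], dir[1], dir[2]);
  double dn = norm3(d); d = scl(d, 1.0 / dn);
  // orthonormal frame
  V3 a = std::fabs(d.x) < 0.9 ? V3(1, 0, 0) : V3(0, 1, 0);
  V3 e1 = cross(d, a); e1 = scl(e1, 1.0 / norm3(e1));
  V3 e2 = cross(d, e1);

  std::vector<V3> TA(nf), TB(nf), TC(nf);
  std::vector<double> u0(nf), u1(nf), v0(nf), v1(nf);
  double gx0 = 1e300, gx1 = -1e300, gy0 = 1e300, gy1 = -1e300;
  for (int f = 0; f < nf; ++f) {
    TA[f] = getrow(V, F(f, 0) - 1); TB[f] = getrow(V, F(f, 1) - 1);
    TC[f] = getrow(V, F(f, 2) - 1);
    double ua = dot(TA[f], e1), ub = dot(TB[f], e1), uc = dot(TC[f], e1);
    double va = dot(TA[f], e2), vb = dot(TB[f], e2), vc = dot(TC[f], e2);
    u0[f] = std::min(ua, std::min(ub, uc)); u1[f] = std::max(ua, std::max(ub, uc));
    v0[f] = std::min(va, std::min(vb, vc)); v1[f] = std::max(va, std::max(vb, vc));
    gx0 = std::min(gx0, u0[f]); gx1 = std::max(gx1, u1[f]);
    gy0 = std::min(gy0, v0[f]); gy1 = std::max(gy1, v1[f]);
  }
  int ncell = std::max(8, (int)std::sqrt((double)nf));
  TriGrid2D g;
  g.nx = ncell; g.ny = ncell;
  g.x0 = gx0; g.y0 = gy0;
  g.hx = std::max((gx1 - gx0) / ncell, 1e-12);
  g.hy = std::max((gy1 - gy0) / ncell, 1e-12);
  g.cells.assign((size_t)ncell * ncell, std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    int i0 = g.cix(u0[f]), i1 = g.cix(u1[f]);
    int j0 = g.ciy(v0[f]), j1 = g.ciy(v1[f]);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        g.cells[(size_t)j * ncell + i].push_back(f);
  }

  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    V3 o = getrow(P, p);
    double pu = dot(o, e1), pv = dot(o, e2);
    if (pu < gx0 - on_tol || pu > gx1 + on_tol || pv < gy0 - on_tol || pv > gy1 + on_tol) {
      out[p] = 0; continue;
    }
    const std::vector<int>& cand = g.cells[(size_t)g.ciy(pv) * g.nx + g.cix(pu)];
    int crossings = 0; bool onsurf = false;
    for (size_t k = 0; k < cand.size(); ++k) {
      int f = cand[k];
      if (pu < u0[f] - 1e-12 || pu > u1[f] + 1e-12 ||
          pv < v0[f] - 1e-12 || pv > v1[f] + 1e-12) continue;
      double t;
      if (!ray_tri(o, d, TA[f], TB[f], TC[f], t)) continue;
      if (std::fabs(t) < on_tol) { onsurf = true; break; }
      if (t > 0) crossings++;
    }
    out[p] = (onsurf || (crossings % 2 == 1)) ? 1 : 0;
  }
  return out;
}

// Eberly-style point-triangle closest point.
static double pt_tri_dist2(const V3& p, const V3& a, const V3& b, const V3& c, V3& cp) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { cp = a; V3 w = sub(p, a); return dot(w, w); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { cp = b; V3 w = sub(p, b); return dot(w, w); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3); cp = add(a, scl(ab, v));
    V3 w = sub(p, cp); return dot(w, w);
  }
  V3 cpv = sub(p, c);
  double d5 = dot(ab, cpv), d6 = dot(ac, cpv);
  if (d6 >= 0 && d5 <= d6) { cp = c; V3 w = sub(p, c); return dot(w, w); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w0 = d2 / (d2 - d6); cp = add(a, scl(ac, w0));
    V3 w = sub(p, cp); return dot(w, w);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w0 = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    cp = add(b, scl(sub(c, b), w0));
    V3 w = sub(p, cp); return dot(w, w);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w0 = vc * denom;
  cp = add(a, add(scl(ab, v), scl(ac, w0)));
  V3 w = sub(p, cp); return dot(w, w);
}

// Closest surface point for each query; brute force over faces with bounding
// box early rejection against the current best radius.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  std::vector<V3> A(nf), B(nf), C(nf);
  std::vector<double> bx0(nf), bx1(nf), by0(nf), by1(nf), bz0(nf), bz1(nf);
  for (int f = 0; f < nf; ++f) {
    A[f] = getrow(V, F(f, 0) - 1); B[f] = getrow(V, F(f, 1) - 1);
    C[f] = getrow(V, F(f, 2) - 1);
    bx0[f] = std::min(A[f].x, std::min(B[f].x, C[f].x));
    bx1[f] = std::max(A[f].x, std::max(B[f].x, C[f].x));
    by0[f] = std::min(A[f].y, std::min(B[f].y, C[f].y));
    by1[f] = std::max(A[f].y, std::max(B[f].y, C[f].y));
    bz0[f] = std::min(A[f].z, std::min(B[f].z, C[f].z));
    bz1[f] = std::max(A[f].z, std::max(B[f].z, C[f].z));
  }
  NumericVector dist(np);
  NumericMatrix cp(np, 3);
  IntegerVector face(np);
  for (int p = 0; p < np; ++p) {
    V3 q = getrow(P, p);
    double best = std::numeric_limits<double>::infinity();
    V3 bestcp; int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      double dx = std::max(std::max(bx0[f] - q.x, q.x - bx1[f]), 0.0);
      double dy = std::max(std::max(by0[f] - q.y, q.y - by1[f]), 0.0);
      double dz = std::max(std::max(bz0[f] - q.z, q.z - bz1[f]), 0.0);
      if (dx * dx + dy * dy + dz * dz >= best) continue;
      V3 c;
      double d2 = pt_tri_dist2(q, A[f], B[f], C[f], c);
      if (d2 < best) { best = d2; bestcp = c; bestf = f; }
    }
    dist[p] = std::sqrt(best);
    cp(p, 0) = bestcp.x; cp(p, 1) = bestcp.y; cp(p, 2) = bestcp.z;
    face[p] = bestf + 1; // 1-based
  }
  return List::create(_["dist"] = dist, _["point"] = cp, _["face"] = face);
}

// ---- Tetrahedral point location with a uniform background grid ----
class TetLocator {
public:
  std::vector<V3> V;
  std::vector<int> T; // 4*K, 0-based
  int K;
  double x0, y0, z0, hx, hy, hz;
  int nx, ny, nz;
  std::vector< std::vector<int> > cells;

  TetLocator(const NumericMatrix& Vm, const IntegerMatrix& Tm) {
    int nv = Vm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = getrow(Vm, i);
    K = Tm.nrow();
    T.resize(4 * (size_t)K);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < 4; ++j) T[4 * (size_t)k + j] = Tm(k, j) - 1;
    double ax0 = 1e300, ax1 = -1e300, ay0 = 1e300, ay1 = -1e300, az0 = 1e300, az1 = -1e300;
    for (int i = 0; i < nv; ++i) {
      ax0 = std::min(ax0, V[i].x); ax1 = std::max(ax1, V[i].x);
      ay0 = std::min(ay0, V[i].y); ay1 = std::max(ay1, V[i].y);
      az0 = std::min(az0, V[i].z); az1 = std::max(az1, V[i].z);
    }
    int n = std::max(4, (int)std::cbrt((double)K / 4.0));
    nx = ny = nz = n;
    x0 = ax0; y0 = ay0; z0 = az0;
    hx = std::max((ax1 - ax0) / n, 1e-12);
    hy = std::max((ay1 - ay0) / n, 1e-12);
    hz = std::max((az1 - az0) / n, 1e-12);
    cells.assign((size_t)n * n * n, std::vector<int>());
    for (int k = 0; k < K; ++k) {
      double tx0 = 1e300, tx1 = -1e300, ty0 = 1e300, ty1 = -1e300, tz0 = 1e300, tz1 = -1e300;
      for (int j = 0; j < 4; ++j) {
        const V3& p = V[T[4 * (size_t)k + j]];
        tx0 = std::min(tx0, p.x); tx1 = std::max(tx1, p.x);
        ty0 = std::min(ty0, p.y); ty1 = std::max(ty1, p.y);
        tz0 = std::min(tz0, p.z); tz1 = std::max(tz1, p.z);
      }
      int i0 = ci(tx0, x0, hx, nx), i1 = ci(tx1, x0, hx, nx);
      int j0 = ci(ty0, y0, hy, ny), j1 = ci(ty1, y0, hy, ny);
      int k0 = ci(tz0, z0, hz, nz), k1 = ci(tz1, z0, hz, nz);
      for (int i = i0; i <= i1; ++i)
        for (int j = j0; j <= j1; ++j)
          for (int l = k0; l <= k1; ++l)
            cells[idx(i, j, l)].push_back(k);
    }
  }
  static inline int ci(double v, double o, double h, int n) {
    int i = (int)std::floor((v - o) / h);
    return std::min(std::max(i, 0), n - 1);
  }
  inline size_t idx(int i, int j, int l) const {
    return ((size_t)l * ny + j) * nx + i;
  }
  // barycentric coordinates of p in tet k
  bool bary(int k, const V3& p, double* w, double slack) const {
    const V3& a = V[T[4 * (size_t)k]];
    const V3& b = V[T[4 * (size_t)k + 1]];
    const V3& c = V[T[4 * (size_t)k + 2]];
    const V3& d = V[T[4 * (size_t)k + 3]];
    V3 e1 = sub(b, a), e2 = sub(c, a), e3 = sub(d, a), ep = sub(p, a);
    double det = dot(e1, cross(e2, e3));
    if (std::fabs(det) < TINY) return false;
    double inv = 1.0 / det;
    double l1 = dot(ep, cross(e2, e3)) * inv;
    double l2 = dot(e1, cross(ep, e3)) * inv;
    double l3 = dot(e1, cross(e2, ep)) * inv;
    double l0 = 1.0 - l1 - l2 - l3;
    if (l0 < -slack || l1 < -slack || l2 < -slack || l3 < -slack) return false;
    w[0] = l0; w[1] = l1; w[2] = l2; w[3] = l3;
    return true;
  }
  int locate(const V3& p, double* w, double slack) const {
    if (p.x < x0 - 10 * hx || p.y < y0 - 10 * hy || p.z < z0 - 10 * hz) return -1;
    int i = ci(p.x, x0, hx, nx), j = ci(p.y, y0, hy, ny), l = ci(p.z, z0, hz, nz);
    const std::vector<int>& cand = cells[idx(i, j, l)];
    for (size_t m = 0; m < cand.size(); ++m)
      if (bary(cand[m], p, w, slack)) return cand[m];
    return -1;
  }
};

// [[Rcpp::export]]
SEXP cpp_build_locator(NumericMatrix V, IntegerMatrix T) {
  XPtr<TetLocator> p(new TetLocator(V, T), true);
  return p;
}

// [[Rcpp::export]]
List cpp_locate_points(SEXP ptr, NumericMatrix P, double slack) {
  XPtr<TetLocator> loc(ptr);
  int np = P.nrow();
  IntegerVector cell(np);
  NumericMatrix bw(np, 4);
  for (int i = 0; i < np; ++i) {
    double w[4];
    int k = loc->locate(getrow(P, i), w, slack);
    cell[i] = k + 1; // 0 if not found
    if (k >= 0) for (int j = 0; j < 4; ++j) bw(i, j) = w[j];
  }
  return List::create(_["cell"] = cell, _["bary"] = bw);
}

// Interpolate a nodal vector field at query points (P1 barycentric).
// Points outside the mesh get the fallback value for that row of `fallback`.
// [[Rcpp::export]]
NumericMatrix cpp_interp_field(SEXP ptr, NumericMatrix U, NumericMatrix P,
                               NumericMatrix fallback, double slack) {
  XPtr<TetLocator> loc(ptr);
  int np = P.nrow(), nc = U.ncol();
  NumericMatrix out(np, nc);
  for (int i = 0; i < np; ++i) {
    double w[4];
    int k = loc->locate(getrow(P, i), w, slack);
    if (k < 0) {
      for (int c = 0; c < nc; ++c) out(i, c) = fallback(i, c);
    } else {
      for (int c = 0; c < nc; ++c) {
        double s = 0;
        for (int j = 0; j < 4; ++j) s += w[j] * U(loc->T[4 * (size_t)k + j], c);
        out(i, c) = s;
      }
    }
  }
  return out;
}

// ---- Lagrangian particle advection through a stored velocity series ----
// U: nV x 3 x nsnap array (snapshots at uniform dt). Boundary faces (BF,
// 0-based into V) carry integer labels; particles leaving through a face
// whose label is in mv_labels are frozen as departed, other exits are
// projected back inside (tangential slide along the wall).
// Returns positions at every snapshot and a status vector (0 alive, 1 departed).
// [[Rcpp::export]]
List cpp_advect_particles(NumericMatrix V, IntegerMatrix T, NumericVector Uarr,
                          IntegerVector Udim, NumericMatrix P0, double dt,
                          IntegerMatrix BF, IntegerVector BFlab,
                          IntegerVector mv_labels) {
  TetLocator loc(V, T);
  int nv = Udim[0], nsnap = Udim[2];
  int np = P0.nrow();
  int nbf = BF.nrow();
  const double* U = REAL(Uarr);
  std::vector<V3> A(nbf), B(nbf), C(nbf), N(nbf);
  for (int f = 0; f < nbf; ++f) {
    A[f] = getrow(V, BF(f, 0) - 1); B[f] = getrow(V, BF(f, 1) - 1);
    C[f] = getrow(V, BF(f, 2) - 1);
    V3 n = cross(sub(B[f], A[f]), sub(C[f], A[f]));
    N[f] = scl(n, 1.0 / std::max(norm3(n), TINY));
  }
  std::vector<bool> is_mv(nbf, false);
  for (int f = 0; f < nbf; ++f)
    for (int m = 0; m < mv_labels.size(); ++m)
      if (BFlab[f] == mv_labels[m]) is_mv[f] = true;

  // u(x, t) with linear time interpolation between snapshots s and s+1
  double slack = 1e-9;
  NumericVector traj(Dimension(np, 3, nsnap));
  IntegerVector status(np, 0);
  std::vector<V3> pos(np);
  for (int i = 0; i < np; ++i) pos[i] = getrow(P0, i);
  for (int i = 0; i < np; ++i) {
    traj[i] = pos[i].x; traj[i + (size_t)np] = pos[i].y; traj[i + 2 * (size_t)np] = pos[i].z;
  }

  for (int s = 0; s < nsnap - 1; ++s) {
    const double* U0 = U + (size_t)s * nv * 3;
    const double* U1 = U + (size_t)(s + 1) * nv * 3;
    for (int i = 0; i < np; ++i) {
      if (status[i] == 1) {
        size_t off = (size_t)(s + 1) * np * 3;
        traj[off + i] = pos[i].x; traj[off + i + np] = pos[i].y; traj[off + i + 2 * (size_t)np] = pos[i].z;
        continue;
      }
      V3 x = pos[i];
      // RK4 with time-interpolated velocity; theta in [0,1] across the step
      V3 k1, k2, k3, k4;
      bool ok = true;
      V3 xs = x;
      for (int stage = 0; stage < 4; ++stage) {
        double th = (stage == 0) ? 0.0 : (stage == 3 ? 1.0 : 0.5);
        V3 xq;
        if (stage == 0) xq = x;
        else if (stage == 1) xq = add(x, scl(k1, 0.5 * dt));
        else if (stage == 2) xq = add(x, scl(k2, 0.5 * dt));
        else xq = add(x, scl(k3, dt));
        double w[4];
        int k = loc.locate(xq, w, slack);
        if (k < 0) k = loc.locate(xq, w, 1e-3); // relaxed retry
        V3 u(0, 0, 0);
        if (k >= 0) {
          for (int j = 0; j < 4; ++j) {
            int vj = loc.T[4 * (size_t)k + j];
            double u0x = U0[vj], u0y = U0[vj + nv], u0z = U0[vj + 2 * (size_t)nv];
            double u1x = U1[vj], u1y = U1[vj + nv], u1z = U1[vj + 2 * (size_t)nv];
            u.x += w[j] * ((1 - th) * u0x + th * u1x);
            u.y += w[j] * ((1 - th) * u0y + th * u1y);
            u.z += w[j] * ((1 - th) * u0z + th * u1z);
          }
        } else ok = false;
        if (stage == 0) k1 = u; else if (stage == 1) k2 = u;
        else if (stage == 2) k3 = u; else k4 = u;
      }
      (void)ok; (void)xs;
      V3 xn = add(x, scl(add(add(k1, scl(k2, 2)), add(scl(k3, 2), k4)), dt / 6.0));
      double w[4];
      if (loc.locate(xn, w, slack) < 0 && loc.locate(xn, w, 1e-6) < 0) {
        // left the mesh: closest boundary face decides the fate
        double best = 1e300; V3 bcp; int bf = -1;
        for (int f = 0; f < nbf; ++f) {
          V3 c;
          double d2 = pt_tri_dist2(xn, A[f], B[f], C[f], c);
          if (d2 < best) { best = d2; bcp = c; bf = f; }
        }
        if (bf >= 0 && is_mv[bf]) {
          status[i] = 1;
          xn = bcp;
        } else if (bf >= 0) {
          // slide back inside: project to wall, nudge along inward normal
          xn = sub(bcp, scl(N[bf], 1e-4));
          if (loc.locate(xn, w, 1e-6) < 0) xn = sub(bcp, scl(N[bf], 1e-3));
          if (loc.locate(xn, w, 1e-6) < 0) xn = x; // give up, stay put
        } else xn = x;
      }
      pos[i] = xn;
      size_t off = (size_t)(s + 1) * np * 3;
      traj[off + i] = xn.x; traj[off + i + np] = xn.y; traj[off + i + 2 * (size_t)np] = xn.z;
    }
  }
  return List::create(_["traj"] = traj, _["status"] = status);
}
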
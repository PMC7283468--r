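// Force kernels and surface-field operators for the discrete-element cell
// model. Positions are N x 3 (m), triangles/edges are 1-based index matrices
// coming from R. All forces are in newtons; forces are the negative gradients
// of the discrete energies so that finite-difference checks apply exactly.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline void getrow(const NumericMatrix& m, int i, double* out) {
  out[0] = m(i, 0); out[1] = m(i, 1); out[2] = m(i, 2);
}

// ---------------------------------------------------------------- springs --

// [[Rcpp::export]]
NumericMatrix cpp_spring_forces(const NumericMatrix& pos,
                                const IntegerMatrix& edges,
                                const NumericVector& rest, double k) {
  int ne = edges.nrow();
  NumericMatrix F(pos.nrow(), 3);
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double d[3] = {pos(j,0) - pos(i,0), pos(j,1) - pos(i,1), pos(j,2) - pos(i,2)};
    double len = norm3(d);
    if (len <= 0) stop("zero-length edge %d", e + 1);
    double fmag = k * (len - rest[e]); // tension when stretched
    for (int c = 0; c < 3; ++c) {
      double f = fmag * d[c] / len;
      F(i, c) += f;  // pulls i toward j when stretched
      F(j, c) -= f;
    }
  }
  return F;
}

// [[Rcpp::export]]
double cpp_spring_energy(const NumericMatrix& pos, const IntegerMatrix& edges,
                         const NumericVector& rest, double k) {
  double E = 0;
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double d[3] = {pos(j,0) - pos(i,0), pos(j,1) - pos(i,1), pos(j,2) - pos(i,2)};
    double len = norm3(d);
    E += 0.5 * k * (len - rest[e]) * (len - rest[e]);
  }
  return E;
}

// Axis-projected dashpot: F_i = -Lambda (n.v_ij) n on node i, opposite on j.
// [[Rcpp::export]]
NumericMatrix cpp_dashpot_forces(const NumericMatrix& pos,
                                 const NumericMatrix& vel,
                                 const IntegerMatrix& edges, double lambda) {
  NumericMatrix F(pos.nrow(), 3);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double d[3] = {pos(j,0) - pos(i,0), pos(j,1) - pos(i,1), pos(j,2) - pos(i,2)};
    double len = norm3(d);
    if (len <= 0) stop("zero-length edge %d", e + 1);
    double n[3] = {d[0] / len, d[1] / len, d[2] / len};
    double vij[3] = {vel(i,0) - vel(j,0), vel(i,1) - vel(j,1), vel(i,2) - vel(j,2)};
    double vproj = dot3(n, vij);
    for (int c = 0; c < 3; ++c) {
      F(i, c) -= lambda * vproj * n[c];
      F(j, c) += lambda * vproj * n[c];
    }
  }
  return F;
}

// ------------------------------------------------------------------- area --

// E = k_loc/2 sum (A - Aref)^2 / Aref + k_glob/2 (Atot - Atot_ref)^2 / Atot_ref
// [[Rcpp::export]]
double cpp_area_energy(const NumericMatrix& pos, const IntegerMatrix& tris,
                       const NumericVector& ref_area, double ref_total,
                       double k_loc, double k_glob) {
  int nt = tris.nrow();
  double E = 0, tot = 0;
  for (int t = 0; t < nt; ++t) {
    double a[3], b[3], c[3];
    getrow(pos, tris(t,0) - 1, a); getrow(pos, tris(t,1) - 1, b);
    getrow(pos, tris(t,2) - 1, c);
    double e1[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double e2[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double n[3]; cross3(e1, e2, n);
    double A = 0.5 * norm3(n);
    tot += A;
    double dA = A - ref_area[t];
    E += 0.5 * k_loc * dA * dA / ref_area[t];
  }
  double dT = tot - ref_total;
  E += 0.5 * k_glob * dT * dT / ref_total;
  return E;
}

// [[Rcpp::export]]
NumericMatrix cpp_area_forces(const NumericMatrix& pos,
                              const IntegerMatrix& tris,
                              const NumericVector& ref_area, double ref_total,
                              double k_loc, double k_glob) {
  int nt = tris.nrow();
  NumericMatrix F(pos.nrow(), 3);
  std::vector<double> A(nt);
  double tot = 0;
  for (int t = 0; t < nt; ++t) {
    double a[3], b[3], c[3];
    getrow(pos, tris(t,0) - 1, a); getrow(pos, tris(t,1) - 1, b);
    getrow(pos, tris(t,2) - 1, c);
    double e1[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double e2[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double n[3]; cross3(e1, e2, n);
    A[t] = 0.5 * norm3(n);
    tot += A[t];
  }
  double glob = k_glob * (tot - ref_total) / ref_total;
  for (int t = 0; t < nt; ++t) {
    int ia = tris(t,0) - 1, ib = tris(t,1) - 1, ic = tris(t,2) - 1;
    double a[3], b[3], c[3];
    getrow(pos, ia, a); getrow(pos, ib, b); getrow(pos, ic, c);
    double e1[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double e2[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double n[3]; cross3(e1, e2, n);
    double nn = norm3(n);
    if (nn <= 0) stop("degenerate triangle %d", t + 1);
    double nh[3] = {n[0]/nn, n[1]/nn, n[2]/nn};
    double coef = k_loc * (A[t] - ref_area[t]) / ref_area[t] + glob;
    // dA/da = 0.5 nh x (c - b), cyclic
    double cb[3] = {c[0]-b[0], c[1]-b[1], c[2]-b[2]};
    double ac[3] = {a[0]-c[0], a[1]-c[1], a[2]-c[2]};
    double ba[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double ga[3], gb[3], gc[3];
    cross3(nh, cb, ga); cross3(nh, ac, gb); cross3(nh, ba, gc);
    for (int k = 0; k < 3; ++k) {
      F(ia, k) -= coef * 0.5 * ga[k];
      F(ib, k) -= coef * 0.5 * gb[k];
      F(ic, k) -= coef * 0.5 * gc[k];
    }
  }
  return F;
}

// ----------------------------------------------------------------- volume --

// [[Rcpp::export]]
double cpp_volume(const NumericMatrix& pos, const IntegerMatrix& tris) {
  double V = 0;
  for (int t = 0; t < tris.nrow(); ++t) {
    double a[3], b[3], c[3];
    getrow(pos, tris(t,0) - 1, a); getrow(pos, tris(t,1) - 1, b);
    getrow(pos, tris(t,2) - 1, c);
    double bc[3]; cross3(b, c, bc);
    V += dot3(a, bc) / 6.0;
  }
  return V;
}

// [[Rcpp::export]]
double cpp_volume_energy(const NumericMatrix& pos, const IntegerMatrix& tris,
                         double ref_volume, double k_vol) {
  double dV = cpp_volume(pos, tris) - ref_volume;
  return 0.5 * k_vol * dV * dV / ref_volume;
}

// [[Rcpp::export]]
NumericMatrix cpp_volume_force(const NumericMatrix& pos,
                               const IntegerMatrix& tris,
                               double ref_volume, double k_vol) {
  NumericMatrix F(pos.nrow(), 3);
  double coef = k_vol * (cpp_volume(pos, tris) - ref_volume) / ref_volume;
  for (int t = 0; t < tris.nrow(); ++t) {
    int ia = tris(t,0) - 1, ib = tris(t,1) - 1, ic = tris(t,2) - 1;
    double a[3], b[3], c[3];
    getrow(pos, ia, a); getrow(pos, ib, b); getrow(pos, ic, c);
    double bc[3], ca[3], ab[3];
    cross3(b, c, bc); cross3(c, a, ca); cross3(a, b, ab);
    for (int k = 0; k < 3; ++k) {
      F(ia, k) -= coef * bc[k] / 6.0;
      F(ib, k) -= coef * ca[k] / 6.0;
      F(ic, k) -= coef * ab[k] / 6.0;
    }
  }
  return F;
}

// ---------------------------------------------------------------- bending --

// Hinge rows: (a, b, o1, o2), triangles (a,b,o1) and (b,a,o2), both CCW from
// outside. Signed dihedral theta via atan2; zero for a flat pair.
static double hinge_theta(const double* x0, const double* x1, const double* x2,
                          const double* x3, double* n1, double* n2, double* e) {
  double e1[3] = {x1[0]-x0[0], x1[1]-x0[1], x1[2]-x0[2]};
  double d2[3] = {x2[0]-x0[0], x2[1]-x0[1], x2[2]-x0[2]};
  double d3[3] = {x3[0]-x1[0], x3[1]-x1[1], x3[2]-x1[2]};
  // n1 = (x1-x0) x (x2-x0) : normal of (x0,x1,x2)
  cross3(e1, d2, n1);
  // n2 = (x0-x1) x (x3-x1) = normal of (x1,x0,x3)
  double me1[3] = {-e1[0], -e1[1], -e1[2]};
  cross3(me1, d3, n2);
  e[0] = e1[0]; e[1] = e1[1]; e[2] = e1[2];
  double n1n = norm3(n1), n2n = norm3(n2), en = norm3(e);
  if (n1n <= 0 || n2n <= 0 || en <= 0) stop("degenerate hinge");
  double cosb = dot3(n1, n2) / (n1n * n2n);
  double cr[3]; cross3(n1, n2, cr);
  double sinb = dot3(cr, e) / (n1n * n2n * en);
  return std::atan2(sinb, cosb);
}

// [[Rcpp::export]]
NumericVector cpp_dihedrals(const NumericMatrix& pos, const IntegerMatrix& hinges) {
  int nh = hinges.nrow();
  NumericVector th(nh);
  for (int h = 0; h < nh; ++h) {
    double x0[3], x1[3], x2[3], x3[3], n1[3], n2[3], e[3];
    getrow(pos, hinges(h,0) - 1, x0); getrow(pos, hinges(h,1) - 1, x1);
    getrow(pos, hinges(h,2) - 1, x2); getrow(pos, hinges(h,3) - 1, x3);
    th[h] = hinge_theta(x0, x1, x2, x3, n1, n2, e);
  }
  return th;
}

// [[Rcpp::export]]
double cpp_bend_energy(const NumericMatrix& pos, const IntegerMatrix& hinges,
                       const NumericVector& theta_ref, double k_bend) {
  NumericVector th = cpp_dihedrals(pos, hinges);
  double E = 0;
  for (int h = 0; h < hinges.nrow(); ++h)
    E += k_bend * (1.0 - std::cos(th[h] - theta_ref[h]));
  return E;
}

// [[Rcpp::export]]
NumericMatrix cpp_bend_forces(const NumericMatrix& pos,
                              const IntegerMatrix& hinges,
                              const NumericVector& theta_ref, double k_bend) {
  NumericMatrix F(pos.nrow(), 3);
  for (int h = 0; h < hinges.nrow(); ++h) {
    int i0 = hinges(h,0) - 1, i1 = hinges(h,1) - 1;
    int i2 = hinges(h,2) - 1, i3 = hinges(h,3) - 1;
    double x0[3], x1[3], x2[3], x3[3], n1[3], n2[3], e[3];
    getrow(pos, i0, x0); getrow(pos, i1, x1);
    getrow(pos, i2, x2); getrow(pos, i3, x3);
    double th = hinge_theta(x0, x1, x2, x3, n1, n2, e);
    double en = norm3(e);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double eh[3] = {e[0]/en, e[1]/en, e[2]/en};
    // gradients of theta (translation/rotation invariant decomposition)
    double g2[3], g3[3], g0[3], g1[3];
    for (int k = 0; k < 3; ++k) {
      g2[k] = en * n1[k] / n1sq;
      g3[k] = en * n2[k] / n2sq;
    }
    double a1 = (x2[0]-x1[0])*eh[0] + (x2[1]-x1[1])*eh[1] + (x2[2]-x1[2])*eh[2];
    double a2 = (x3[0]-x1[0])*eh[0] + (x3[1]-x1[1])*eh[1] + (x3[2]-x1[2])*eh[2];
    double b1 = (x0[0]-x2[0])*eh[0] + (x0[1]-x2[1])*eh[1] + (x0[2]-x2[2])*eh[2];
    double b2 = (x0[0]-x3[0])*eh[0] + (x0[1]-x3[1])*eh[1] + (x0[2]-x3[2])*eh[2];
    for (int k = 0; k < 3; ++k) {
      g0[k] = a1 * n1[k] / n1sq + a2 * n2[k] / n2sq;
      g1[k] = b1 * n1[k] / n1sq + b2 * n2[k] / n2sq;
    }
    // force = -dE/dx; the gradient decomposition above carries an overall
    // sign fixed by the atan2 orientation convention of hinge_theta
    double coef = k_bend * std::sin(th - theta_ref[h]);
    for (int k = 0; k < 3; ++k) {
      F(i0, k) += coef * g0[k];
      F(i1, k) += coef * g1[k];
      F(i2, k) += coef * g2[k];
      F(i3, k) += coef * g3[k];
    }
  }
  return F;
}

// --------------------------------------------------- surface actin field --

// Finite-volume weights w = (shared edge length) / (centroid distance) for
// each triangle/neighbor pair; tri_adj is T x 3 (1-based neighbor ids).
// [[Rcpp::export]]
NumericMatrix cpp_fv_weights(const NumericMatrix& pos, const IntegerMatrix& tris,
                             const IntegerMatrix& tri_adj) {
  int nt = tris.nrow();
  NumericMatrix W(nt, 3);
  std::vector<double> cx(nt), cy(nt), cz(nt);
  for (int t = 0; t < nt; ++t) {
    double a[3], b[3], c[3];
    getrow(pos, tris(t,0) - 1, a); getrow(pos, tris(t,1) - 1, b);
    getrow(pos, tris(t,2) - 1, c);
    cx[t] = (a[0]+b[0]+c[0])/3; cy[t] = (a[1]+b[1]+c[1])/3; cz[t] = (a[2]+b[2]+c[2])/3;
  }
  for (int t = 0; t < nt; ++t) {
    int v[3] = {tris(t,0), tris(t,1), tris(t,2)};
    for (int s = 0; s < 3; ++s) {
      int u = tri_adj(t, s) - 1;
      if (u < 0) { W(t, s) = 0; continue; }
      // shared edge = the two vertices common to t and u
      int shared[2], m = 0;
      for (int k = 0; k < 3 && m < 2; ++k) {
        int vv = v[k];
        if (vv == tris(u,0) || vv == tris(u,1) || vv == tris(u,2)) shared[m++] = vv;
      }
      if (m < 2) stop("triangle adjacency inconsistent");
      double p[3], q[3];
      getrow(pos, shared[0] - 1, p); getrow(pos, shared[1] - 1, q);
      double elen = std::sqrt((p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                              (p[2]-q[2])*(p[2]-q[2]));
      double dc = std::sqrt((cx[t]-cx[u])*(cx[t]-cx[u]) + (cy[t]-cy[u])*(cy[t]-cy[u]) +
                            (cz[t]-cz[u])*(cz[t]-cz[u]));
      W(t, s) = elen / dc;
    }
  }
  return W;
}

// Explicit finite-volume step of dG/dt = kgen 1[src] - kdeg G + D lap(G),
// with nsub sub-cycles. Nonnegativity is preserved under the stability bound.
// [[Rcpp::export]]
NumericVector cpp_actin_step(const NumericVector& G, const IntegerMatrix& tri_adj,
                             const NumericMatrix& W, const NumericVector& areas,
                             const LogicalVector& source, double kgen,
                             double kdeg, double D, double dt, int nsub) {
  int nt = G.size();
  NumericVector cur = clone(G), nxt(nt);
  double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    for (int t = 0; t < nt; ++t) {
      double diff = 0;
      for (int k = 0; k < 3; ++k) {
        int u = tri_adj(t, k) - 1;
        if (u >= 0) diff += W(t, k) * (cur[u] - cur[t]);
      }
      double dG = (source[t] ? kgen : 0.0) - kdeg * cur[t] + D * diff / areas[t];
      nxt[t] = cur[t] + h * dG;
      if (nxt[t] < 0) nxt[t] = 0;
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Largest stable explicit step for the current geometry.
// [[Rcpp::export]]
double cpp_actin_stable_dt(const IntegerMatrix& tri_adj, const NumericMatrix& W,
                           const NumericVector& areas, double kdeg, double D) {
  double worst = R_PosInf;
  for (int t = 0; t < tri_adj.nrow(); ++t) {
    double wsum = 0;
    for (int k = 0; k < 3; ++k)
      if (tri_adj(t, k) > 0) wsum += W(t, k);
    double rate = kdeg + D * wsum / areas[t];
    if (rate > 0 && 1.0 / rate < worst) worst = 1.0 / rate;
  }
  return worst;
}

// In-plane least-squares gradient of a per-triangle field from neighbor
// centroid differences; rows are 3-vectors lying in each triangle's plane.
// [[Rcpp::export]]
NumericMatrix cpp_tri_gradients(const NumericMatrix& pos, const IntegerMatrix& tris,
                                const IntegerMatrix& tri_adj, const NumericVector& G) {
  int nt = tris.nrow();
  NumericMatrix grad(nt, 3);
  std::vector<double> cx(nt), cy(nt), cz(nt);
  for (int t = 0; t < nt; ++t) {
    double a[3], b[3], c[3];
    getrow(pos, tris(t,0) - 1, a); getrow(pos, tris(t,1) - 1, b);
    getrow(pos, tris(t,2) - 1, c);
    cx[t] = (a[0]+b[0]+c[0])/3; cy[t] = (a[1]+b[1]+c[1])/3; cz[t] = (a[2]+b[2]+c[2])/3;
  }
  for (int t = 0; t < nt; ++t) {
    double a[3], b[3], c[3];
    getrow(pos, tris(t,0) - 1, a); getrow(pos, tris(t,1) - 1, b);
    getrow(pos, tris(t,2) - 1, c);
    double e1[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double e2[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double n[3]; cross3(e1, e2, n);
    double nn = norm3(n);
    if (nn <= 0) stop("degenerate triangle %d", t + 1);
    // orthonormal in-plane basis (u, v)
    double u[3] = {e1[0], e1[1], e1[2]};
    double un = norm3(u);
    for (int k = 0; k < 3; ++k) u[k] /= un;
    double nv[3] = {n[0]/nn, n[1]/nn, n[2]/nn};
    double v[3]; cross3(nv, u, v);
    // 2x2 normal equations
    double a11 = 0, a12 = 0, a22 = 0, r1 = 0, r2 = 0;
    for (int s = 0; s < 3; ++s) {
      int q = tri_adj(t, s) - 1;
      if (q < 0) continue;
      double d[3] = {cx[q]-cx[t], cy[q]-cy[t], cz[q]-cz[t]};
      double du = dot3(d, u), dv = dot3(d, v);
      double dg = G[q] - G[t];
      a11 += du * du; a12 += du * dv; a22 += dv * dv;
      r1 += du * dg; r2 += dv * dg;
    }
    double det = a11 * a22 - a12 * a12;
    if (std::fabs(det) < 1e-30) continue; // leave zero
    double gu = (a22 * r1 - a12 * r2) / det;
    double gv = (a11 * r2 - a12 * r1) / det;
    for (int k = 0; k < 3; ++k) grad(t, k) = gu * u[k] + gv * v[k];
  }
  return grad;
}

// ---------------------------------------------------------------- contact --

// Dugdale cohesive-zone (Maugis) sphere-on-flat normal force in the
// Derjaguin/DMT regime: Hertzian repulsive core plus a constant adhesive
// stress sigma0 = w/h0 acting over the finite range h0. gap < 0 is overlap.
// Returns the force on the sphere along the plane normal (positive = pushed
// away from the plane). Exact Hertz for w = 0.
// [[Rcpp::export]]
double cpp_md_force(double gap, double R_eff, double E_star, double w, double h0) {
  if (!(R_eff > 0)) stop("R_eff must be positive");
  if (gap >= h0) return 0.0;
  double adh = (h0 > 0 && w > 0) ? -2.0 * M_PI * R_eff * (w / h0) *
                                     (h0 - std::max(gap, 0.0)) : 0.0;
  if (w > 0 && h0 <= 0) adh = -2.0 * M_PI * R_eff * w; // zero-range limit
  double rep = 0.0;
  if (gap < 0) rep = (4.0 / 3.0) * E_star * std::sqrt(R_eff) * std::pow(-gap, 1.5);
  if (w <= 0 && gap >= 0) return 0.0;
  return rep + adh;
}

// Sphere radius through >=4 points (algebraic least-squares); returns Inf
// for near-planar sets, used per contacting triangle with its edge-neighbor
// stencil.
static double fit_radius(const std::vector<double>& px, const std::vector<double>& py,
                         const std::vector<double>& pz, double r_cap) {
  int n = px.size();
  double mx = 0, my = 0, mz = 0;
  for (int i = 0; i < n; ++i) { mx += px[i]; my += py[i]; mz += pz[i]; }
  mx /= n; my /= n; mz /= n;
  // normal equations for |x|^2 = 2 c.x + d on centered coords
  double A[4][4] = {{0}}, b[4] = {0};
  for (int i = 0; i < n; ++i) {
    double x = px[i]-mx, y = py[i]-my, z = pz[i]-mz;
    double row[4] = {2*x, 2*y, 2*z, 1.0};
    double rhs = x*x + y*y + z*z;
    for (int r = 0; r < 4; ++r) {
      for (int c = 0; c < 4; ++c) A[r][c] += row[r]*row[c];
      b[r] += row[r]*rhs;
    }
  }
  // Gaussian elimination with partial pivoting
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    for (int r = c+1; r < 4; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
    if (std::fabs(A[piv][c]) < 1e-300) return R_PosInf;
    if (piv != c) {
      for (int k = 0; k < 4; ++k) std::swap(A[c][k], A[piv][k]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c+1; r < 4; ++r) {
      double f = A[r][c] / A[c][c];
      for (int k = c; k < 4; ++k) A[r][k] -= f * A[c][k];
      b[r] -= f * b[c];
    }
  }
  double sol[4];
  for (int r = 3; r >= 0; --r) {
    double s = b[r];
    for (int k = r+1; k < 4; ++k) s -= A[r][k] * sol[k];
    sol[r] = s / A[r][r];
  }
  double r2 = sol[0]*sol[0] + sol[1]*sol[1] + sol[2]*sol[2] + sol[3];
  if (!(r2 > 0)) return R_PosInf;
  double r = std::sqrt(r2);
  return (r > r_cap) ? R_PosInf : r;
}

// [[Rcpp::export]]
double cpp_fit_radius_points(const NumericMatrix& pts, double r_cap) {
  std::vector<double> px, py, pz;
  for (int i = 0; i < pts.nrow(); ++i) {
    px.push_back(pts(i,0)); py.push_back(pts(i,1)); pz.push_back(pts(i,2));
  }
  return fit_radius(px, py, pz, r_cap);
}

// --------------------------------------------- friction operator / solver --

// y = M v with M = Gamma_liquid I + Gamma_subs diag(contact) +
//               sum_edges Lambda_d n n^T (v_i - v_j) structure.
static void friction_apply(const NumericMatrix& pos, const IntegerMatrix& edges,
                           const IntegerVector& contact, double lambda_d,
                           double gamma_subs, double gamma_liquid,
                           const std::vector<double>& v, std::vector<double>& y) {
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    double g = gamma_liquid + (contact[i] ? gamma_subs : 0.0);
    y[3*i] = g * v[3*i]; y[3*i+1] = g * v[3*i+1]; y[3*i+2] = g * v[3*i+2];
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e,0) - 1, j = edges(e,1) - 1;
    double d[3] = {pos(j,0)-pos(i,0), pos(j,1)-pos(i,1), pos(j,2)-pos(i,2)};
    double len = norm3(d);
    if (len <= 0) continue;
    double nh[3] = {d[0]/len, d[1]/len, d[2]/len};
    double rel[3] = {v[3*i]-v[3*j], v[3*i+1]-v[3*j+1], v[3*i+2]-v[3*j+2]};
    double p = lambda_d * dot3(nh, rel);
    for (int k = 0; k < 3; ++k) {
      y[3*i+k] += p * nh[k];
      y[3*j+k] -= p * nh[k];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_friction_matvec(const NumericMatrix& pos, const IntegerMatrix& edges,
                                  const IntegerVector& contact, double lambda_d,
                                  double gamma_subs, double gamma_liquid,
                                  const NumericMatrix& v) {
  int n = pos.nrow();
  std::vector<double> vv(3*n), yy(3*n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) vv[3*i+k] = v(i,k);
  friction_apply(pos, edges, contact, lambda_d, gamma_subs, gamma_liquid, vv, yy);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i,k) = yy[3*i+k];
  return out;
}

// Jacobi-preconditioned conjugate gradient for M v = F; v0 is the warm start.
static int cg_solve(const NumericMatrix& pos, const IntegerMatrix& edges,
                    const IntegerVector& contact, double lambda_d,
                    double gamma_subs, double gamma_liquid,
                    const std::vector<double>& F, std::vector<double>& v,
                    double tol, int maxit) {
  int n3 = F.size();
  std::vector<double> r(n3), z(n3), p(n3), Ap(n3), dinv(n3);
  int n = n3 / 3;
  // diagonal of M for the preconditioner
  std::vector<double> diag(n3);
  for (int i = 0; i < n; ++i) {
    double g = gamma_liquid + (contact[i] ? gamma_subs : 0.0);
    diag[3*i] = diag[3*i+1] = diag[3*i+2] = g;
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e,0) - 1, j = edges(e,1) - 1;
    double d[3] = {pos(j,0)-pos(i,0), pos(j,1)-pos(i,1), pos(j,2)-pos(i,2)};
    double len = norm3(d);
    if (len <= 0) continue;
    for (int k = 0; k < 3; ++k) {
      double nk2 = (d[k]/len) * (d[k]/len);
      diag[3*i+k] += lambda_d * nk2;
      diag[3*j+k] += lambda_d * nk2;
    }
  }
  for (int i = 0; i < n3; ++i) dinv[i] = 1.0 / diag[i];
  friction_apply(pos, edges, contact, lambda_d, gamma_subs, gamma_liquid, v, Ap);
  double f2 = 0;
  for (int i = 0; i < n3; ++i) { r[i] = F[i] - Ap[i]; f2 += F[i]*F[i]; }
  double tol2 = tol * tol * (f2 > 0 ? f2 : 1.0);
  double rz = 0;
  for (int i = 0; i < n3; ++i) { z[i] = dinv[i]*r[i]; rz += r[i]*z[i]; p[i] = z[i]; }
  int it = 0;
  for (; it < maxit; ++it) {
    double r2 = 0;
    for (int i = 0; i < n3; ++i) r2 += r[i]*r[i];
    if (r2 <= tol2) break;
    friction_apply(pos, edges, contact, lambda_d, gamma_subs, gamma_liquid, p, Ap);
    double pAp = 0;
    for (int i = 0; i < n3; ++i) pAp += p[i]*Ap[i];
    if (pAp <= 0) stop("friction operator is not positive definite");
    double alpha = rz / pAp;
    for (int i = 0; i < n3; ++i) { v[i] += alpha*p[i]; r[i] -= alpha*Ap[i]; }
    double rznew = 0;
    for (int i = 0; i < n3; ++i) { z[i] = dinv[i]*r[i]; rznew += r[i]*z[i]; }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n3; ++i) p[i] = z[i] + beta*p[i];
  }
  return it;
}

// [[Rcpp::export]]
NumericMatrix cpp_solve_velocities(const NumericMatrix& pos, const IntegerMatrix& edges,
                                   const IntegerVector& contact, double lambda_d,
                                   double gamma_subs, double gamma_liquid,
                                   const NumericMatrix& F, const NumericMatrix& v0,
                                   double tol = 1e-10, int maxit = 1000) {
  int n = pos.nrow();
  std::vector<double> Fv(3*n), v(3*n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Fv[3*i+k] = F(i,k); v[3*i+k] = v0(i,k); }
  cg_solve(pos, edges, contact, lambda_d, gamma_subs, gamma_liquid, Fv, v, tol, maxit);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i,k) = v[3*i+k];
  return out;
}
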
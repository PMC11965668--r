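// Staggered-grid (MAC) finite-volume kernels for the incompressible
// Navier-Stokes solver on masked voxel domains.
//
// Layout: cell-centred pressure, face-centred velocity components
//   u: (nx+1, ny, nz) on x-faces; v: (nx, ny+1, nz); w: (nx, ny, nz+1).
// Cell codes: 0 fluid, 1 solid, >= 2 port-ghost (2 + port index).
// Momentum right-hand side: conservative QUICK advection (first-order
// upwind fallback where the quadratic stencil would reach into the solid)
// plus explicit diffusion with sub-voxel wall-distance (theta) corrected
// one-sided stencils, so the no-slip plane sits on the true wall rather
// than the stair-step face. Ports are handled through ghost cells filled
// by mac_apply_bc: prescribed-velocity ports impose the (possibly
// profiled) axial velocity; pressure ports copy the interior solution
// (zero gradient) and receive their Dirichlet value in the projection.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Box {
  int nx, ny, nz;
  const int* code;
  int cc(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 1;
    return code[i + (size_t)nx * (j + (size_t)ny * k)];
  }
  size_t cidx(int i, int j, int k) const {
    return i + (size_t)nx * (j + (size_t)ny * k);
  }
};

// face-array geometry for one velocity component
struct Comp {
  int d0, d1, d2;      // array dims (cells + 1 along own axis)
  const double* val;
  const double* phi;
  int axis;            // 0, 1 or 2
  bool in(int f0, int f1, int f2) const {
    return f0 >= 0 && f1 >= 0 && f2 >= 0 && f0 < d0 && f1 < d1 && f2 < d2;
  }
  size_t idx(int f0, int f1, int f2) const {
    return f0 + (size_t)d0 * (f1 + (size_t)d1 * f2);
  }
  double at(int f0, int f1, int f2) const {
    return in(f0, f1, f2) ? val[idx(f0, f1, f2)] : 0.0;
  }
  double phiat(int f0, int f1, int f2) const {
    return in(f0, f1, f2) ? phi[idx(f0, f1, f2)] : 1e30;
  }
};

// is the value stored at this face meaningful (fluid DOF, wall zero with a
// wall lying between the adjacent cells, or a ghost-managed port value)?
inline bool face_ok(const Box& B, const Comp& C, int g[3]) {
  int cm[3] = {g[0], g[1], g[2]};
  cm[C.axis] -= 1;
  int a = B.cc(cm[0], cm[1], cm[2]);
  int b = B.cc(g[0], g[1], g[2]);
  return a == 0 || b == 0 || a >= 2 || b >= 2;
}

inline double quick_face(double C, double D, double U, bool okU) {
  return okU ? (0.75 * C + 0.375 * D - 0.125 * U) : C;
}

inline double theta_frac(const Comp& C, const int g[3], const int gn[3]) {
  double pa = C.phiat(g[0], g[1], g[2]);
  double pn = C.phiat(gn[0], gn[1], gn[2]);
  if (!std::isfinite(pa) || !std::isfinite(pn) || pn <= pa) return 0.5;
  double th = pa / (pa - pn);
  if (!std::isfinite(th)) th = 0.5;
  if (th < 0.1) th = 0.1;
  if (th > 1.0) th = 1.0;
  return th;
}

} // namespace

// quadratic upwind face value
static inline double qk(double C, double D, double U) {
  return 0.75 * C + 0.375 * D - 0.125 * U;
}

// [[Rcpp::export(name = ".mac_rhs")]]
void mac_rhs(NumericVector u, NumericVector v, NumericVector w,
             IntegerVector code, IntegerVector dims,
             NumericVector phiu, NumericVector phiv, NumericVector phiw,
             double nu, double h, double fx,
             NumericVector du, NumericVector dv, NumericVector dw,
             List fast_idx, List slow_idx) {
  Box B{dims[0], dims[1], dims[2], INTEGER(code)};
  Comp comps[3] = {
    {dims[0] + 1, dims[1], dims[2], REAL(u), REAL(phiu), 0},
    {dims[0], dims[1] + 1, dims[2], REAL(v), REAL(phiv), 1},
    {dims[0], dims[1], dims[2] + 1, REAL(w), REAL(phiw), 2}};
  double* outs[3] = {REAL(du), REAL(dv), REAL(dw)};
  const double h2 = h * h;
  std::memset(REAL(du), 0, sizeof(double) * du.size());
  std::memset(REAL(dv), 0, sizeof(double) * dv.size());
  std::memset(REAL(dw), 0, sizeof(double) * dw.size());

  // fast path: full QUICK/Laplacian stencil known to be valid
  for (int a = 0; a < 3; ++a) {
    const Comp& A = comps[a];
    const double* AV = A.val;
    double* out = outs[a];
    const int sA[3] = {1, A.d0, A.d0 * A.d1};
    IntegerVector fidx = fast_idx[a];
    const int* F = INTEGER(fidx);
    const int nF = fidx.size();
    const double bf = (a == 0) ? fx : 0.0;
    // strides of the two transverse components' face arrays and the
    // base offset mapping cell (i,j,k) -> lower b-face linear index
    for (int t = 0; t < nF; ++t) {
      const int fi = F[t];
      const double uc = AV[fi];
      int f0 = fi % A.d0;
      int rem = fi / A.d0;
      int f1 = rem % A.d1;
      int f2 = rem / A.d1;
      double adv = 0.0;
      {
        const int s = sA[a];
        // axial fluxes at the two adjacent cell centres
        double uaP = 0.5 * (AV[fi] + AV[fi + s]);
        double valP = uaP >= 0 ? qk(AV[fi], AV[fi + s], AV[fi - s])
                               : qk(AV[fi + s], AV[fi], AV[fi + 2 * s]);
        double uaM = 0.5 * (AV[fi - s] + AV[fi]);
        double valM = uaM >= 0 ? qk(AV[fi - s], AV[fi], AV[fi - 2 * s])
                               : qk(AV[fi], AV[fi - s], AV[fi + s]);
        adv += uaP * valP - uaM * valM;
      }
      for (int tt = 1; tt < 3; ++tt) {
        const int b = (a + tt) % 3;
        const Comp& Bc = comps[b];
        const double* BV = Bc.val;
        const int sBb = (b == 0) ? 1 : (b == 1 ? Bc.d0 : Bc.d0 * Bc.d1);
        const int sb = sA[b];
        // cell coords: cp = (f0,f1,f2) - e_a applied only along a for cm
        int c0 = f0, c1 = f1, c2 = f2;
        int m0 = f0, m1 = f1, m2 = f2;
        if (a == 0) m0 -= 1; else if (a == 1) m1 -= 1; else m2 -= 1;
        const int ibp = c0 + Bc.d0 * (c1 + Bc.d1 * c2);
        const int ibm = m0 + Bc.d0 * (m1 + Bc.d1 * m2);
        double vbM = 0.5 * (BV[ibm] + BV[ibp]);
        double vbP = 0.5 * (BV[ibm + sBb] + BV[ibp + sBb]);
        double valP = vbP >= 0
          ? qk(AV[fi], AV[fi + sb], AV[fi - sb])
          : qk(AV[fi + sb], AV[fi], AV[fi + 2 * sb]);
        double valM = vbM >= 0
          ? qk(AV[fi - sb], AV[fi], AV[fi - 2 * sb])
          : qk(AV[fi], AV[fi - sb], AV[fi + sb]);
        adv += vbP * valP - vbM * valM;
      }
      double lap = (AV[fi - sA[0]] + AV[fi + sA[0]] +
                    AV[fi - sA[1]] + AV[fi + sA[1]] +
                    AV[fi - sA[2]] + AV[fi + sA[2]] - 6.0 * uc) / h2;
      out[fi] = -adv / h + nu * lap + bf;
    }
  }

  // checked path: faces whose stencil touches walls or the box rim
  for (int a = 0; a < 3; ++a) {
    const Comp& A = comps[a];
    double* out = outs[a];
    int ea[3] = {0, 0, 0}; ea[a] = 1;
    IntegerVector sidx = slow_idx[a];
    const int* S = INTEGER(sidx);
    const int nS = sidx.size();
    for (int t = 0; t < nS; ++t) {
      const int fi = S[t];
      int f0 = fi % A.d0;
      int rem = fi / A.d0;
      int f1 = rem % A.d1;
      int f2 = rem / A.d1;
      int g[3] = {f0, f1, f2};
      int cm[3] = {g[0] - ea[0], g[1] - ea[1], g[2] - ea[2]};
      double uc = A.val[fi];
      double adv = 0.0;

      // streamwise flux difference: fluxes at the centres of cells cm, cp
      for (int s = 0; s < 2; ++s) {   // s=0 -> cell cm, s=1 -> cell cp
        int q[3] = {g[0] + (s - 1) * ea[0], g[1] + (s - 1) * ea[1],
                    g[2] + (s - 1) * ea[2]};
        int gl[3] = {q[0], q[1], q[2]};                  // lower own-face
        int gu[3] = {q[0] + ea[0], q[1] + ea[1], q[2] + ea[2]};
        double ua = 0.5 * (A.at(gl[0], gl[1], gl[2]) +
                           A.at(gu[0], gu[1], gu[2]));
        double val;
        if (ua >= 0) {
          int gU[3] = {gl[0] - ea[0], gl[1] - ea[1], gl[2] - ea[2]};
          val = quick_face(A.at(gl[0], gl[1], gl[2]),
                           A.at(gu[0], gu[1], gu[2]),
                           A.at(gU[0], gU[1], gU[2]),
                           face_ok(B, A, gU));
        } else {
          int gU[3] = {gu[0] + ea[0], gu[1] + ea[1], gu[2] + ea[2]};
          val = quick_face(A.at(gu[0], gu[1], gu[2]),
                           A.at(gl[0], gl[1], gl[2]),
                           A.at(gU[0], gU[1], gU[2]),
                           face_ok(B, A, gU));
        }
        adv += (s == 0 ? -1.0 : 1.0) * ua * val;
      }

      // transverse flux differences at the two corner pairs
      for (int t = 1; t < 3; ++t) {
        int b = (a + t) % 3;
        const Comp& Bc = comps[b];
        int eb[3] = {0, 0, 0}; eb[b] = 1;
        double Fcorner[2];
        for (int s = 0; s < 2; ++s) {  // s=0 lower corner, s=1 upper
          // advecting component b, averaged over the two b-faces that
          // meet this corner (one per adjacent cell of face g)
          int q1[3] = {cm[0] + s * eb[0], cm[1] + s * eb[1],
                       cm[2] + s * eb[2]};
          int q2[3] = {g[0] + s * eb[0], g[1] + s * eb[1],
                       g[2] + s * eb[2]};
          double vb = 0.5 * (Bc.at(q1[0], q1[1], q1[2]) +
                             Bc.at(q2[0], q2[1], q2[2]));
          // advected component a interpolated along b across the corner
          int glo[3] = {g[0] + (s - 1) * eb[0], g[1] + (s - 1) * eb[1],
                        g[2] + (s - 1) * eb[2]};
          int ghi[3] = {glo[0] + eb[0], glo[1] + eb[1], glo[2] + eb[2]};
          double val;
          if (vb >= 0) {
            int gU[3] = {glo[0] - eb[0], glo[1] - eb[1], glo[2] - eb[2]};
            val = quick_face(A.at(glo[0], glo[1], glo[2]),
                             A.at(ghi[0], ghi[1], ghi[2]),
                             A.at(gU[0], gU[1], gU[2]),
                             face_ok(B, A, gU));
          } else {
            int gU[3] = {ghi[0] + eb[0], ghi[1] + eb[1], ghi[2] + eb[2]};
            val = quick_face(A.at(ghi[0], ghi[1], ghi[2]),
                             A.at(glo[0], glo[1], glo[2]),
                             A.at(gU[0], gU[1], gU[2]),
                             face_ok(B, A, gU));
          }
          Fcorner[s] = vb * val;
        }
        adv += Fcorner[1] - Fcorner[0];
      }
      adv /= h;

      // diffusion with theta-corrected one-sided wall stencils
      double lap = 0.0;
      for (int d3 = 0; d3 < 3; ++d3) {
        int ed[3] = {0, 0, 0}; ed[d3] = 1;
        int gm[3] = {g[0] - ed[0], g[1] - ed[1], g[2] - ed[2]};
        int gp[3] = {g[0] + ed[0], g[1] + ed[1], g[2] + ed[2]};
        bool vm = face_ok(B, A, gm), vp = face_ok(B, A, gp);
        double um = A.at(gm[0], gm[1], gm[2]);
        double up = A.at(gp[0], gp[1], gp[2]);
        if (vm && vp) {
          lap += (um + up - 2.0 * uc) / h2;
        } else if (vm && !vp) {
          double bw = theta_frac(A, g, gp) * h;
          lap += 2.0 * (um * bw - uc * (h + bw)) / (h * bw * (h + bw));
        } else if (!vm && vp) {
          double bw = theta_frac(A, g, gm) * h;
          lap += 2.0 * (up * bw - uc * (h + bw)) / (h * bw * (h + bw));
        } else {
          double bm = theta_frac(A, g, gm) * h;
          double bp = theta_frac(A, g, gp) * h;
          lap += -2.0 * uc / (bm * bp);
        }
      }
      out[fi] = -adv + nu * lap + (a == 0 ? fx : 0.0);
    }
  }
}

// [[Rcpp::export(name = ".mac_apply_bc")]]
void mac_apply_bc(NumericVector u, NumericVector v, NumericVector w,
                  IntegerVector code, IntegerVector dims,
                  IntegerVector port_kind, IntegerVector port_dir,
                  NumericVector port_val, NumericVector wu) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Box B{nx, ny, nz, INTEGER(code)};
  double* U = REAL(u); double* V = REAL(v); double* W = REAL(w);
  const double* WU = REAL(wu);
  auto iu = [&](int i, int j, int k) {
    return (size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k); };
  auto iv = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k); };
  auto iw = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k); };

  for (int k = 0; k < nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i) {
    int c = B.cc(i, j, k);
    if (c < 2) continue;
    int p = c - 2;
    if (port_kind[p] == 0) {          // prescribed axial velocity
      double val = port_val[p];
      U[iu(i, j, k)] = val * WU[iu(i, j, k)];
      U[iu(i + 1, j, k)] = val * WU[iu(i + 1, j, k)];
      V[iv(i, j, k)] = 0.0; V[iv(i, j + 1, k)] = 0.0;
      W[iw(i, j, k)] = 0.0; W[iw(i, j, k + 1)] = 0.0;
    } else {                          // pressure port: zero-gradient copy
      int d = port_dir[p];
      int m = i;
      int guard = 0;
      while (B.cc(m, j, k) != 0 && guard++ < 8) m += d;
      if (B.cc(m, j, k) != 0) continue;   // no fluid in this column
      if (d > 0) {
        // interior at +x: plane face iu(m), interior face iu(m+1)
        U[iu(m, j, k)] = U[iu(m + 1, j, k)];
        U[iu(i, j, k)] = U[iu(m, j, k)];
        U[iu(i + 1, j, k)] = U[iu(m, j, k)];
      } else {
        U[iu(m + 1, j, k)] = U[iu(m, j, k)];
        U[iu(i, j, k)] = U[iu(m + 1, j, k)];
        U[iu(i + 1, j, k)] = U[iu(m + 1, j, k)];
      }
      V[iv(i, j, k)] = V[iv(m, j, k)];
      V[iv(i, j + 1, k)] = V[iv(m, j + 1, k)];
      W[iw(i, j, k)] = W[iw(m, j, k)];
      W[iw(i, j, k + 1)] = W[iw(m, j, k + 1)];
    }
  }
}

// [[Rcpp::export(name = ".mac_divergence")]]
void mac_divergence(NumericVector u, NumericVector v, NumericVector w,
                    IntegerVector code, IntegerVector cellid,
                    IntegerVector dims, double h, NumericVector div) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* U = REAL(u); const double* V = REAL(v);
  const double* W = REAL(w);
  const int* cid = INTEGER(cellid);
  const int* cd = INTEGER(code);
  double* D = REAL(div);
  for (int k = 0; k < nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i) {
    size_t ci = i + (size_t)nx * (j + (size_t)ny * k);
    if (cd[ci] != 0) continue;
    size_t u0 = i + (size_t)(nx + 1) * (j + (size_t)ny * k);
    size_t v0 = i + (size_t)nx * (j + (size_t)(ny + 1) * k);
    size_t w0 = i + (size_t)nx * (j + (size_t)ny * k);
    size_t wk = i + (size_t)nx * (j + (size_t)ny * (k + 1));
    D[cid[ci] - 1] = (U[u0 + 1] - U[u0] + V[v0 + nx] - V[v0] +
                      W[wk] - W[w0]) / h;
  }
}

// [[Rcpp::export(name = ".mac_correct")]]
void mac_correct(NumericVector u, NumericVector v, NumericVector w,
                 NumericVector q, IntegerVector code, IntegerVector cellid,
                 IntegerVector dims, double dt, double h,
                 IntegerVector port_kind, NumericVector port_q) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Box B{nx, ny, nz, INTEGER(code)};
  const int* cid = INTEGER(cellid);
  const double* Q = REAL(q);
  double* U = REAL(u); double* V = REAL(v); double* W = REAL(w);
  double r = dt / h;

  // x faces
  for (int k = 0; k < nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i <= nx; ++i) {
    int cl = B.cc(i - 1, j, k), cr = B.cc(i, j, k);
    size_t fi = i + (size_t)(nx + 1) * (j + (size_t)ny * k);
    if (cl == 0 && cr == 0) {
      U[fi] -= r * (Q[cid[B.cidx(i, j, k)] - 1] -
                    Q[cid[B.cidx(i - 1, j, k)] - 1]);
    } else if (cl == 0 && cr >= 2 && port_kind[cr - 2] == 1) {
      double qc = Q[cid[B.cidx(i - 1, j, k)] - 1];
      double qg = 2.0 * port_q[cr - 2] - qc;
      U[fi] -= r * (qg - qc);
    } else if (cr == 0 && cl >= 2 && port_kind[cl - 2] == 1) {
      double qc = Q[cid[B.cidx(i, j, k)] - 1];
      double qg = 2.0 * port_q[cl - 2] - qc;
      U[fi] -= r * (qc - qg);
    }
  }
  // y faces
  for (int k = 0; k < nz; ++k)
  for (int j = 0; j <= ny; ++j)
  for (int i = 0; i < nx; ++i) {
    if (B.cc(i, j - 1, k) == 0 && B.cc(i, j, k) == 0) {
      size_t fi = i + (size_t)nx * (j + (size_t)(ny + 1) * k);
      V[fi] -= r * (Q[cid[B.cidx(i, j, k)] - 1] -
                    Q[cid[B.cidx(i, j - 1, k)] - 1]);
    }
  }
  // z faces
  for (int k = 0; k <= nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i) {
    if (B.cc(i, j, k - 1) == 0 && B.cc(i, j, k) == 0) {
      size_t fi = i + (size_t)nx * (j + (size_t)ny * k);
      W[fi] -= r * (Q[cid[B.cidx(i, j, k)] - 1] -
                    Q[cid[B.cidx(i, j, k - 1)] - 1]);
    }
  }
}

// [[Rcpp::export(name = ".mac_axpy")]]
void mac_axpy(NumericVector y, NumericVector x, double s) {
  double* Y = REAL(y); const double* X = REAL(x);
  R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) Y[i] += s * X[i];
}

// [[Rcpp::export(name = ".mac_copy_axpy")]]
void mac_copy_axpy(NumericVector out, NumericVector base, NumericVector x,
                   double s) {
  double* O = REAL(out); const double* Bp = REAL(base);
  const double* X = REAL(x);
  R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) O[i] = Bp[i] + s * X[i];
}

// [[Rcpp::export(name = ".mac_maxabs")]]
double mac_maxabs(NumericVector x) {
  const double* X = REAL(x);
  R_xlen_t n = x.size();
  double m = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = std::fabs(X[i]);
    if (a > m) m = a;
  }
  return m;
}
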
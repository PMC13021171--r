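// Element kernels for the total-Lagrangian tetrahedral solver.
//
// Conventions: length mm, stress kPa, force mN. Symmetric tensors travel as
// Voigt 6-vectors (11, 22, 33, 12, 13, 23) holding tensor (not engineering)
// components. Element tangents are forward-difference derivatives of the
// exact internal force, which keeps the stress implementation the single
// source of truth.

#include <RcppArmadillo.h>
using namespace Rcpp;

struct MatDef {
  int model;        // 0 = Yeoh, 1 = Ogden (FEBio convention)
  double k;         // bulk modulus (kPa)
  arma::vec c, m;
};

static MatDef parse_mat(const NumericVector& code) {
  MatDef M;
  M.model = (int)code[0];
  M.k = code[1];
  int N = (int)code[2];
  M.c.set_size(N);
  for (int i = 0; i < N; ++i) M.c[i] = code[3 + i];
  if (M.model == 1) {
    M.m.set_size(N);
    for (int i = 0; i < N; ++i) M.m[i] = code[3 + N + i];
  }
  return M;
}

// Isochoric and volumetric second Piola-Kirchhoff stress from C = F^T F.
// Returns false on a non-positive Jacobian.
static bool pk2_parts(const arma::mat33& C, const MatDef& M,
                      arma::mat33& Siso, arma::mat33& Svol, double& J) {
  double detC = arma::det(C);
  if (!(detC > 0.0)) return false;
  J = std::sqrt(detC);
  arma::mat33 Cinv = arma::inv_sympd(C);
  if (M.model == 0) {
    double I1 = arma::trace(C);
    double I1b = std::pow(J, -2.0 / 3.0) * I1;
    double psi1 = 0.0, x = I1b - 3.0, p = 1.0;
    for (arma::uword i = 0; i < M.c.n_elem; ++i) {
      psi1 += M.c[i] * (double)(i + 1) * p;
      p *= x;
    }
    Siso = 2.0 * psi1 * std::pow(J, -2.0 / 3.0) *
      (arma::mat33(arma::fill::eye) - (I1 / 3.0) * Cinv);
  } else {
    arma::vec3 ev; arma::mat33 V;
    arma::eig_sym(ev, V, C);
    arma::vec3 lam = arma::sqrt(arma::clamp(ev, 1e-300, arma::datum::inf));
    double Jm13 = std::pow(J, -1.0 / 3.0);
    arma::vec3 beta(arma::fill::zeros);
    for (arma::uword i = 0; i < M.c.n_elem; ++i)
      for (int a = 0; a < 3; ++a)
        beta[a] += M.c[i] / M.m[i] * std::pow(Jm13 * lam[a], M.m[i]);
    double mb = arma::mean(beta);
    Siso.zeros();
    for (int a = 0; a < 3; ++a)
      Siso += (beta[a] - mb) / (lam[a] * lam[a]) * (V.col(a) * V.col(a).t());
  }
  Svol = M.k * std::log(J) * Cinv;
  return true;
}

static inline arma::mat33 voigt2mat(const double* v) {
  arma::mat33 S;
  S(0,0)=v[0]; S(1,1)=v[1]; S(2,2)=v[2];
  S(0,1)=S(1,0)=v[3]; S(0,2)=S(2,0)=v[4]; S(1,2)=S(2,1)=v[5];
  return S;
}
static inline void mat2voigt(const arma::mat33& S, double* v) {
  v[0]=S(0,0); v[1]=S(1,1); v[2]=S(2,2); v[3]=S(0,1); v[4]=S(0,2); v[5]=S(1,2);
}

// Quadrature and shape data -------------------------------------------------

// tet10 quadrature (4 points, degree 2), natural coords (L2, L3, L4).
static const double QA = 0.5854101966249685, QB = 0.1381966011250105;
static const double qpts[4][3] = {
  {QB, QB, QB}, {QA, QB, QB}, {QB, QA, QB}, {QB, QB, QA}};

// tet10 shape function derivatives wrt (r,s,t); node order: 4 corners
// (1..4) then edges (12,13,14,23,24,34) as midside nodes 5..10.
static void tet10_dshape(double r, double s, double t, double dN[10][3]) {
  double L1 = 1.0 - r - s - t, L2 = r, L3 = s, L4 = t;
  // corners: N = L(2L-1); dN/dL = 4L-1
  double d1 = 4.0 * L1 - 1.0, d2 = 4.0 * L2 - 1.0,
         d3 = 4.0 * L3 - 1.0, d4 = 4.0 * L4 - 1.0;
  // dL1/dr = -1 etc.
  dN[0][0] = -d1; dN[0][1] = -d1; dN[0][2] = -d1;
  dN[1][0] =  d2; dN[1][1] = 0;   dN[1][2] = 0;
  dN[2][0] =  0;  dN[2][1] = d3;  dN[2][2] = 0;
  dN[3][0] =  0;  dN[3][1] = 0;   dN[3][2] = d4;
  // edge 12: 4 L1 L2
  dN[4][0] = 4.0 * (L1 - L2); dN[4][1] = -4.0 * L2; dN[4][2] = -4.0 * L2;
  // edge 13: 4 L1 L3
  dN[5][0] = -4.0 * L3; dN[5][1] = 4.0 * (L1 - L3); dN[5][2] = -4.0 * L3;
  // edge 14: 4 L1 L4
  dN[6][0] = -4.0 * L4; dN[6][1] = -4.0 * L4; dN[6][2] = 4.0 * (L1 - L4);
  // edge 23: 4 L2 L3
  dN[7][0] = 4.0 * L3; dN[7][1] = 4.0 * L2; dN[7][2] = 0;
  // edge 24: 4 L2 L4
  dN[8][0] = 4.0 * L4; dN[8][1] = 0; dN[8][2] = 4.0 * L2;
  // edge 34: 4 L3 L4
  dN[9][0] = 0; dN[9][1] = 4.0 * L4; dN[9][2] = 4.0 * L3;
}

struct ViscoDef {
  arma::vec gamma, tau;
  bool active;
};

// Compute element internal force. Xe: nen x 3 reference coords, Ue: nen x 3
// displacements. state row layout per qp: [S_prev(6) | H_1(6) ... H_nv(6)].
// If update_state, writes new state rows and accumulates mean fields.
static bool elem_force(const arma::mat& Xe, const arma::mat& Ue,
                       const MatDef& M, double lam_g, double lam_ax,
                       const arma::vec3* growth_dir,
                       const ViscoDef& V, double dt,
                       const arma::mat& state_prev, arma::mat& state_new,
                       arma::vec& f, double& minJ,
                       bool update_state, arma::vec* fields) {
  const int nen = Xe.n_rows;
  const int nqp = (nen == 4) ? 1 : 4;
  const int nv = V.active ? (int)V.gamma.n_elem : 0;
  f.zeros(3 * nen);
  minJ = arma::datum::inf;
  arma::mat33 Fdef, C, Ce, Siso, Svol, Sdev, S, P;
  arma::mat33 Emean(arma::fill::zeros);
  double Jmean = 0.0, Vtot = 0.0;

  for (int q = 0; q < nqp; ++q) {
    arma::mat dNdX(nen, 3);
    double wdet;
    if (nen == 4) {
      arma::mat33 Jm;
      for (int a = 0; a < 3; ++a)
        Jm.col(a) = (Xe.row(a + 1) - Xe.row(0)).t();
      double dj = arma::det(Jm);
      if (!(std::abs(dj) > 0)) return false;
      arma::mat33 Jinv = arma::inv(Jm);
      // dN in natural coords: N1 = 1-r-s-t, N2=r, N3=s, N4=t
      arma::mat dNn(4, 3);
      dNn.row(0) = arma::rowvec({-1, -1, -1});
      dNn.row(1) = arma::rowvec({1, 0, 0});
      dNn.row(2) = arma::rowvec({0, 1, 0});
      dNn.row(3) = arma::rowvec({0, 0, 1});
      dNdX = dNn * Jinv;            // column-convention: dN_a/dX_j
      wdet = dj / 6.0;
    } else {
      double dN[10][3];
      tet10_dshape(qpts[q][0], qpts[q][1], qpts[q][2], dN);
      arma::mat dNn(10, 3);
      for (int a = 0; a < 10; ++a)
        for (int j = 0; j < 3; ++j) dNn(a, j) = dN[a][j];
      arma::mat33 Jm = Xe.t() * dNn;   // J_ij = dX_i/dr_j
      double dj = arma::det(Jm);
      if (!(std::abs(dj) > 0)) return false;
      dNdX = dNn * arma::inv(Jm);
      wdet = dj / 24.0;   // natural tet volume 1/6, weight 1/4 each
    }
    // deformation gradient
    Fdef = arma::mat33(arma::fill::eye) + (Ue.t() * dNdX);
    double Jf = arma::det(Fdef);
    if (Jf < minJ) minJ = Jf;
    if (!(Jf > 0)) return false;
    // multiplicative growth: elastic part F_e = F F_g^{-1}. F_g is
    // transversely isotropic about the (optional) growth direction d:
    // stretch lam_ax along d, lam_g transverse; without d, isotropic lam_g.
    arma::mat33 Fginv, Fe;
    double detFg;
    if (growth_dir && lam_ax != lam_g) {
      const arma::vec3& gd = *growth_dir;
      Fginv = arma::mat33(arma::fill::eye) / lam_g +
        (1.0 / lam_ax - 1.0 / lam_g) * (gd * gd.t());
      detFg = lam_ax * lam_g * lam_g;
    } else {
      Fginv = arma::mat33(arma::fill::eye) / lam_g;
      detFg = lam_g * lam_g * lam_g;
    }
    Fe = Fdef * Fginv;
    Ce = Fe.t() * Fe;
    double Je;
    if (!pk2_parts(Ce, M, Siso, Svol, Je)) return false;
    // viscoelastic deviatoric update (exponential recursion, midpoint)
    Sdev = Siso;
    if (nv > 0 && dt > 0 && arma::is_finite(dt)) {
      const double* sp = state_prev.colptr(0) + q * (6 * (1 + nv));
      arma::mat33 Sprev = voigt2mat(sp);
      arma::mat33 dS = Siso - Sprev;
      for (int i = 0; i < nv; ++i) {
        arma::mat33 Hi = voigt2mat(sp + 6 * (1 + i));
        arma::mat33 Hnew = std::exp(-dt / V.tau[i]) * Hi +
          V.gamma[i] * std::exp(-dt / (2.0 * V.tau[i])) * dS;
        Sdev += Hnew;
        if (update_state) {
          double* sn = state_new.colptr(0) + q * (6 * (1 + nv));
          mat2voigt(Hnew, sn + 6 * (1 + i));
        }
      }
      if (update_state) {
        double* sn = state_new.colptr(0) + q * (6 * (1 + nv));
        mat2voigt(Siso, sn);
      }
    } else if (nv > 0 && update_state) {
      // relaxed / instantaneous bookkeeping: store current elastic stress,
      // decay history fully when dt is infinite
      double* sn = state_new.colptr(0) + q * (6 * (1 + nv));
      mat2voigt(Siso, sn);
      for (int i = 0; i < nv; ++i) {
        arma::mat33 z(arma::fill::zeros);
        mat2voigt(z, sn + 6 * (1 + i));
      }
    }
    S = Sdev + Svol;
    // reference first Piola with growth: P = det(Fg) F_e S F_g^{-1}
    P = detFg * Fe * S * Fginv;
    for (int a = 0; a < nen; ++a)
      f.subvec(3 * a, 3 * a + 2) += wdet * (P * dNdX.row(a).t());
    if (update_state && fields) {
      C = Fdef.t() * Fdef;
      Emean += wdet * 0.5 * (C - arma::mat33(arma::fill::eye));
      Jmean += wdet * Jf;
      Vtot += wdet;
    }
  }
  if (update_state && fields) {
    Emean /= Vtot; Jmean /= Vtot;
    (*fields)[0] = Emean(0,0); (*fields)[1] = Emean(1,1);
    (*fields)[2] = Emean(2,2); (*fields)[3] = Emean(0,1);
    (*fields)[4] = Emean(0,2); (*fields)[5] = Emean(1,2);
    (*fields)[6] = Jmean;
    (*fields)[7] = Vtot;   // reference volume
  }
  return true;
}

// [[Rcpp::export(name = ".assemble_fem")]]
List assemble_fem(const NumericMatrix& X0, const NumericMatrix& U,
                  const IntegerMatrix& elems, const IntegerVector& mat_id,
                  const List& mats, const List& prony,
                  const NumericVector& lambda_g,
                  const NumericVector& lambda_ax,
                  const NumericVector& growth_dir,
                  const NumericMatrix& state,
                  double dt, bool want_stiffness, bool want_fields) {
  arma::vec3 gd;
  const arma::vec3* gdp = nullptr;
  if (growth_dir.size() == 3) {
    gd = {growth_dir[0], growth_dir[1], growth_dir[2]};
    double nrm = arma::norm(gd);
    if (nrm > 0) { gd /= nrm; gdp = &gd; }
  }
  const int nel = elems.nrow(), nen = elems.ncol();
  const int nqp = (nen == 4) ? 1 : 4;
  const int ndof_node = 3;
  const int ndof = X0.nrow() * ndof_node;

  std::vector<MatDef> M;
  std::vector<ViscoDef> VD;
  for (int i = 0; i < mats.size(); ++i) {
    M.push_back(parse_mat(mats[i]));
    ViscoDef v;
    List p = prony[i];
    NumericVector g = p["gamma"], t = p["tau"];
    v.gamma = arma::vec(g.begin(), g.size());
    v.tau = arma::vec(t.begin(), t.size());
    v.active = g.size() > 0;
    VD.push_back(v);
  }

  arma::vec R(ndof, arma::fill::zeros);
  NumericMatrix state_new(clone(state));
  NumericMatrix fields(nel, 8);
  double minJ_all = arma::datum::inf;
  bool ok = true;
  int bad_el = -1;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_stiffness) {
    ti.reserve((size_t)nel * 3 * nen * 3 * nen);
    tj.reserve((size_t)nel * 3 * nen * 3 * nen);
    tx.reserve((size_t)nel * 3 * nen * 3 * nen);
  }

  arma::mat Xe(nen, 3), Ue(nen, 3);
  arma::vec f0, f1;
  arma::vec fld(8);

  for (int e = 0; e < nel && ok; ++e) {
    for (int a = 0; a < nen; ++a) {
      int n = elems(e, a) - 1;
      for (int j = 0; j < 3; ++j) {
        Xe(a, j) = X0(n, j);
        Ue(a, j) = U(n, j);
      }
    }
    const MatDef& me = M[mat_id[e] - 1];
    const ViscoDef& ve = VD[mat_id[e] - 1];
    int srow = 6 * (1 + (ve.active ? ve.gamma.n_elem : 0));
    arma::mat sp(srow, 1), sn(srow, 1);
    // state matrix layout: nel rows x (nqp * srow_max) cols
    arma::mat spfull(nqp * srow, 1), snfull(nqp * srow, 1);
    for (int q = 0; q < nqp * srow; ++q) spfull(q, 0) = state(e, q);
    snfull = spfull;
    double minJ;
    const arma::vec3* gde = gdp;
    double lax = lambda_ax.size() ? lambda_ax[e] : lambda_g[e];
    bool good = elem_force(Xe, Ue, me, lambda_g[e], lax, gde, ve, dt,
                           spfull, snfull, f0, minJ, true, &fld);
    if (!good) { ok = false; bad_el = e + 1; break; }
    if (minJ < minJ_all) minJ_all = minJ;
    for (int q = 0; q < nqp * srow; ++q) state_new(e, q) = snfull(q, 0);
    if (want_fields)
      for (int j = 0; j < 8; ++j) fields(e, j) = fld[j];
    for (int a = 0; a < nen; ++a) {
      int n = elems(e, a) - 1;
      for (int j = 0; j < 3; ++j) R[3 * n + j] += f0[3 * a + j];
    }
    if (want_stiffness) {
      // forward-difference element tangent
      double h = 1e-6 * std::max(1.0, std::cbrt(std::abs(fld[7])));
      arma::mat dummy(nqp * srow, 1);
      for (int b = 0; b < nen; ++b) {
        for (int j = 0; j < 3; ++j) {
          arma::mat Up = Ue;
          Up(b, j) += h;
          double mj;
          if (!elem_force(Xe, Up, me, lambda_g[e], lax, gde, ve, dt,
                          spfull, dummy, f1, mj, false, nullptr)) {
            // perturbed state inadmissible; use backward difference
            Up(b, j) -= 2 * h;
            if (!elem_force(Xe, Up, me, lambda_g[e], lax, gde, ve, dt,
                            spfull, dummy, f1, mj, false, nullptr)) {
              ok = false; bad_el = e + 1; break;
            }
            f1 = 2.0 * f0 - f1;   // mirror
          }
          int col = 3 * (elems(e, b) - 1) + j;
          for (int a = 0; a < nen; ++a) {
            int rn = 3 * (elems(e, a) - 1);
            for (int i2 = 0; i2 < 3; ++i2) {
              ti.push_back(rn + i2 + 1);
              tj.push_back(col + 1);
              tx.push_back((f1[3 * a + i2] - f0[3 * a + i2]) / h);
            }
          }
        }
        if (!ok) break;
      }
    }
  }

  List out = List::create(
    _["ok"] = ok, _["bad_element"] = bad_el,
    _["residual"] = NumericVector(R.begin(), R.end()),
    _["min_J"] = minJ_all,
    _["state"] = state_new,
    _["fields"] = fields);
  if (want_stiffness) {
    out["Ki"] = IntegerVector(ti.begin(), ti.end());
    out["Kj"] = IntegerVector(tj.begin(), tj.end());
    out["Kx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// [[Rcpp::export(name = ".elem_volumes")]]
NumericVector elem_volumes(const NumericMatrix& X, const IntegerMatrix& elems) {
  int nel = elems.nrow();
  int nen = elems.ncol();
  NumericVector V(nel);
  for (int e = 0; e < nel; ++e) {
    if (nen == 4) {
      arma::mat33 Jm;
      for (int a = 0; a < 3; ++a)
        for (int j = 0; j < 3; ++j)
          Jm(j, a) = X(elems(e, a + 1) - 1, j) - X(elems(e, 0) - 1, j);
      V[e] = arma::det(Jm) / 6.0;
    } else {
      // tet10: 4-point quadrature of det(dX/dr)
      double vol = 0.0;
      arma::mat Xe(10, 3);
      for (int a = 0; a < 10; ++a)
        for (int j = 0; j < 3; ++j) Xe(a, j) = X(elems(e, a) - 1, j);
      for (int q = 0; q < 4; ++q) {
        double dN[10][3];
        tet10_dshape(qpts[q][0], qpts[q][1], qpts[q][2], dN);
        arma::mat dNn(10, 3);
        for (int a = 0; a < 10; ++a)
          for (int j = 0; j < 3; ++j) dNn(a, j) = dN[a][j];
        arma::mat33 Jm = Xe.t() * dNn;
        vol += arma::det(Jm) / 24.0;
      }
      V[e] = vol;
    }
  }
  return V;
}

// Minimum distance from each query point to a triangulated surface.
// [[Rcpp::export(name = ".point_surface_dist")]]
NumericVector point_surface_dist(const NumericMatrix& P,
                                 const NumericMatrix& V,
                                 const IntegerMatrix& Tri) {
  int np = P.nrow(), nt = Tri.nrow();
  NumericVector out(np);
  std::vector<arma::vec3> a(nt), ab(nt), ac(nt);
  for (int t = 0; t < nt; ++t) {
    arma::vec3 va = {V(Tri(t,0)-1,0), V(Tri(t,0)-1,1), V(Tri(t,0)-1,2)};
    arma::vec3 vb = {V(Tri(t,1)-1,0), V(Tri(t,1)-1,1), V(Tri(t,1)-1,2)};
    arma::vec3 vc = {V(Tri(t,2)-1,0), V(Tri(t,2)-1,1), V(Tri(t,2)-1,2)};
    a[t] = va; ab[t] = vb - va; ac[t] = vc - va;
  }
  for (int i = 0; i < np; ++i) {
    arma::vec3 p = {P(i,0), P(i,1), P(i,2)};
    double best = arma::datum::inf;
    for (int t = 0; t < nt; ++t) {
      // closest point on triangle (Ericson, Real-Time Collision Detection)
      arma::vec3 ap = p - a[t];
      double d1 = arma::dot(ab[t], ap), d2 = arma::dot(ac[t], ap);
      double q;
      if (d1 <= 0 && d2 <= 0) {
        q = arma::dot(ap, ap);
      } else {
        arma::vec3 bp = ap - ab[t];
        double d3 = arma::dot(ab[t], bp), d4 = arma::dot(ac[t], bp);
        if (d3 >= 0 && d4 <= d3) {
          q = arma::dot(bp, bp);
        } else {
          arma::vec3 cp = ap - ac[t];
          double d5 = arma::dot(ab[t], cp), d6 = arma::dot(ac[t], cp);
          if (d6 >= 0 && d5 <= d6) {
            q = arma::dot(cp, cp);
          } else {
            double vc_ = d1 * d4 - d3 * d2;
            if (vc_ <= 0 && d1 >= 0 && d3 <= 0) {
              double v = d1 / (d1 - d3);
              arma::vec3 d = ap - v * ab[t];
              q = arma::dot(d, d);
            } else {
              double vb_ = d5 * d2 - d1 * d6;
              if (vb_ <= 0 && d2 >= 0 && d6 <= 0) {
                double w = d2 / (d2 - d6);
                arma::vec3 d = ap - w * ac[t];
                q = arma::dot(d, d);
              } else {
                double va_ = d3 * d6 - d5 * d4;
                if (va_ <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
                  double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
                  arma::vec3 d = p - (a[t] + ab[t] + w * (ac[t] - ab[t]));
                  q = arma::dot(d, d);
                } else {
                  double denom = 1.0 / (va_ + vb_ + vc_);
                  double v = vb_ * denom, w = vc_ * denom;
                  arma::vec3 d = ap - v * ab[t] - w * ac[t];
                  q = arma::dot(d, d);
                }
              }
            }
          }
        }
      }
      if (q < best) best = q;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
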
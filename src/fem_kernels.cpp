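// Element-level kernels for the nonlinear forward solver.
//
// Hexahedra: total-Lagrangian 8-node bricks. The nearly-incompressible
// Neo-Hookean material splits the energy into an isochoric term integrated
// at 2x2x2 Gauss points and a volumetric penalty integrated at the element
// center (selective reduced integration, which avoids volumetric locking as
// nu -> 0.5). Saint Venant-Kirchhoff uses full 2x2x2 integration.
//
// Triangles: 3-node constant-strain membranes with an exactly
// plane-stress-incompressible Neo-Hookean law (the thickness stretch is
// eliminated through 1/det(C)).
//
// Element tangents are consistent to first order: forward finite
// differences of the analytic residual, column by column. At the mesh
// sizes this package targets the O(n_dof) extra residual evaluations per
// element are negligible, and the approach keeps every constitutive
// variant exactly consistent with its residual.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double GP = 0.5773502691896258; // 1/sqrt(3)

// dN/dxi for the standard hex8 trilinear element, rows = nodes
static void hex_dshape(double xi, double eta, double ze, mat &dN) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int i = 0; i < 8; ++i) {
    dN(i, 0) = 0.125 * sx[i] * (1 + sy[i] * eta) * (1 + sz[i] * ze);
    dN(i, 1) = 0.125 * sy[i] * (1 + sx[i] * xi) * (1 + sz[i] * ze);
    dN(i, 2) = 0.125 * sz[i] * (1 + sx[i] * xi) * (1 + sy[i] * eta);
  }
}

static void hex_shape(double xi, double eta, double ze, vec &N) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int i = 0; i < 8; ++i)
    N(i) = 0.125 * (1 + sx[i] * xi) * (1 + sy[i] * eta) * (1 + sz[i] * ze);
}

typedef mat::fixed<3, 3> M33;
typedef mat::fixed<8, 3> M83;
typedef mat::fixed<3, 8> M38;

// reference-configuration cache for one hex: shape gradients and Jacobian
// determinants at the 8 Gauss points plus the center point
struct HexRef {
  M83 dNdX[9];
  double detJ0[9];
  bool ok;
};

static void hex_reference(const mat &Xe, HexRef &ref) {
  static const double gp[2] = {-GP, GP};
  mat dN(8, 3), J0(3, 3);
  ref.ok = true;
  int k = 0;
  for (int a = 0; a < 2; ++a) for (int b = 0; b < 2; ++b) for (int c = 0; c < 2; ++c) {
    hex_dshape(gp[a], gp[b], gp[c], dN);
    J0 = Xe.t() * dN;
    ref.detJ0[k] = det(J0);
    if (ref.detJ0[k] <= 0) { ref.ok = false; return; }
    ref.dNdX[k] = dN * inv(J0);
    ++k;
  }
  hex_dshape(0.0, 0.0, 0.0, dN);
  J0 = Xe.t() * dN;
  ref.detJ0[8] = det(J0);
  if (ref.detJ0[8] <= 0) { ref.ok = false; return; }
  ref.dNdX[8] = dN * inv(J0);
}

// explicit 3x3 determinant and transposed inverse (no heap traffic)
static inline double det3(const M33 &A) {
  return A(0, 0) * (A(1, 1) * A(2, 2) - A(1, 2) * A(2, 1)) -
         A(0, 1) * (A(1, 0) * A(2, 2) - A(1, 2) * A(2, 0)) +
         A(0, 2) * (A(1, 0) * A(2, 1) - A(1, 1) * A(2, 0));
}

static inline void invT3(const M33 &A, double detA, M33 &AiT) {
  double id = 1.0 / detA;
  AiT(0, 0) = (A(1, 1) * A(2, 2) - A(1, 2) * A(2, 1)) * id;
  AiT(1, 0) = -(A(0, 1) * A(2, 2) - A(0, 2) * A(2, 1)) * id;
  AiT(2, 0) = (A(0, 1) * A(1, 2) - A(0, 2) * A(1, 1)) * id;
  AiT(0, 1) = -(A(1, 0) * A(2, 2) - A(1, 2) * A(2, 0)) * id;
  AiT(1, 1) = (A(0, 0) * A(2, 2) - A(0, 2) * A(2, 0)) * id;
  AiT(2, 1) = -(A(0, 0) * A(1, 2) - A(0, 2) * A(1, 0)) * id;
  AiT(0, 2) = (A(1, 0) * A(2, 1) - A(1, 1) * A(2, 0)) * id;
  AiT(1, 2) = -(A(0, 0) * A(2, 1) - A(0, 1) * A(2, 0)) * id;
  AiT(2, 2) = (A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0)) * id;
  // note: result indexed as the transpose of the inverse
}

// residual (8x3 nodal internal forces) of one hex element
// model: 0 = Neo-Hookean isochoric + volumetric penalty, 1 = StVK
static void hex_residual(const HexRef &ref, const M38 &uet, double mu,
                         double kappa, double lambda, int model, M83 &fe,
                         bool &ok) {
  fe.zeros();
  ok = true;
  M33 F, P, FinvT;
  if (model == 0) {
    // isochoric part, full integration
    for (int k = 0; k < 8; ++k) {
      F = uet * ref.dNdX[k];
      F(0, 0) += 1; F(1, 1) += 1; F(2, 2) += 1;
      double J = det3(F);
      if (J <= 0) { ok = false; return; }
      invT3(F, J, FinvT);
      double I1 = accu(F % F);
      double Jm23 = std::pow(J, -2.0 / 3.0);
      P = (mu * Jm23) * F - (mu * Jm23 * I1 / 3.0) * FinvT;
      fe += ref.detJ0[k] * (ref.dNdX[k] * P.t());
    }
    // volumetric penalty, reduced (single center point, weight 8)
    F = uet * ref.dNdX[8];
    F(0, 0) += 1; F(1, 1) += 1; F(2, 2) += 1;
    double J = det3(F);
    if (J <= 0) { ok = false; return; }
    invT3(F, J, FinvT);
    P = (kappa * (J - 1.0) * J) * FinvT;
    fe += (8.0 * ref.detJ0[8]) * (ref.dNdX[8] * P.t());
  } else {
    for (int k = 0; k < 8; ++k) {
      F = uet * ref.dNdX[k];
      F(0, 0) += 1; F(1, 1) += 1; F(2, 2) += 1;
      M33 E = 0.5 * (F.t() * F);
      E(0, 0) -= 0.5; E(1, 1) -= 0.5; E(2, 2) -= 0.5;
      double ltr = lambda * (E(0, 0) + E(1, 1) + E(2, 2));
      M33 S = 2.0 * mu * E;
      S(0, 0) += ltr; S(1, 1) += ltr; S(2, 2) += ltr;
      P = F * S;
      fe += ref.detJ0[k] * (ref.dNdX[k] * P.t());
    }
  }
}

// reference cache for one membrane triangle
struct TriRef {
  mat Gi;      // inverse in-plane reference metric map (2x2)
  double Aref; // reference area
  bool ok;
};

static void tri_reference(const mat &Xe, TriRef &ref) {
  ref.ok = true;
  vec G1 = (Xe.row(1) - Xe.row(0)).t();
  vec G2 = (Xe.row(2) - Xe.row(0)).t();
  double A2 = norm(cross(G1, G2));
  if (A2 <= 0) { ref.ok = false; return; }
  ref.Aref = 0.5 * A2;
  vec e1 = normalise(G1);
  vec e2 = normalise(G2 - dot(G2, e1) * e1);
  mat Gm(2, 2, fill::zeros);
  Gm(0, 0) = dot(G1, e1); Gm(0, 1) = dot(G2, e1); Gm(1, 1) = dot(G2, e2);
  ref.Gi = inv(Gm);
}

// residual (3x3 nodal internal forces) of one membrane triangle
static void tri_residual(const TriRef &ref, const mat &Xe, const mat &ue,
                         double mu, double thick, mat &fe, bool &ok) {
  fe.zeros(3, 3);
  ok = true;
  mat xe = Xe + ue;
  mat g(3, 2);
  g.col(0) = (xe.row(1) - xe.row(0)).t();
  g.col(1) = (xe.row(2) - xe.row(0)).t();
  mat F = g * ref.Gi;             // 3x2
  mat C = F.t() * F;              // 2x2
  double dC = det(C);
  if (dC <= 1e-12) { ok = false; return; }
  mat P = thick * mu * (F - (1.0 / dC) * F * inv(C)); // 3x2, dW/dF
  mat H = ref.Aref * P * ref.Gi.t();  // 3x2
  fe.row(1) = H.col(0).t();
  fe.row(2) = H.col(1).t();
  fe.row(0) = -(fe.row(1) + fe.row(2));
}

// [[Rcpp::export]]
arma::vec hex_volumes_cpp(const arma::mat &nodes, const arma::imat &elems) {
  int ne = elems.n_rows;
  vec out(ne, fill::zeros);
  static const double gp[2] = {-GP, GP};
  mat dN(8, 3), Xe(8, 3);
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < 8; ++i) Xe.row(i) = nodes.row(elems(e, i) - 1);
    double v = 0;
    for (int a = 0; a < 2; ++a) for (int b = 0; b < 2; ++b) for (int c = 0; c < 2; ++c) {
      hex_dshape(gp[a], gp[b], gp[c], dN);
      v += det(Xe.t() * dN);
    }
    out(e) = v;
  }
  return out;
}

// Assemble internal forces and (optionally) the FD tangent, either as
// triplets or - when `dense` - as a full matrix (cheaper below ~2000 dofs).
// u is node-major (3 dofs per node), elems 1-based.
// [[Rcpp::export]]
Rcpp::List assemble_internal_cpp(const arma::mat &nodes, const arma::imat &elems,
                                 const arma::vec &u, const arma::vec &mu,
                                 const arma::vec &kappa, const arma::vec &lambda,
                                 const arma::ivec &model, const arma::vec &thickness,
                                 int etype, bool want_tangent, bool dense = false) {
  int nn = nodes.n_rows, ne = elems.n_rows;
  int npe = (etype == 0) ? 8 : 3; // nodes per element
  int ndof = npe * 3;
  vec fint(3 * nn, fill::zeros);
  bool allok = true;

  mat Kd;
  if (want_tangent && dense) Kd.zeros(3 * nn, 3 * nn);
  std::vector<double> ti, tj, tv;
  if (want_tangent && !dense) { ti.reserve(ne * ndof * ndof); tj.reserve(ne * ndof * ndof); tv.reserve(ne * ndof * ndof); }

  mat Xe(npe, 3), ue(npe, 3), fe(npe, 3), fep(npe, 3), fem(npe, 3), uep(npe, 3);
  M38 uet, uetp;
  M83 hfe, hfep, hfem;
  HexRef href;
  TriRef tref;
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < npe; ++i) {
      int nd = elems(e, i) - 1;
      Xe.row(i) = nodes.row(nd);
      for (int a = 0; a < 3; ++a) ue(i, a) = u(3 * nd + a);
    }
    bool ok = true;
    if (etype == 0) {
      hex_reference(Xe, href);
      if (!href.ok) { allok = false; break; }
      uet = ue.t();
      hex_residual(href, uet, mu(e), kappa(e), lambda(e), model(e), hfe, ok);
      fe = hfe;
    } else {
      tri_reference(Xe, tref);
      if (!tref.ok) { allok = false; break; }
      tri_residual(tref, Xe, ue, mu(e), thickness(e), fe, ok);
    }
    if (!ok) { allok = false; break; }
    for (int i = 0; i < npe; ++i) {
      int nd = elems(e, i) - 1;
      for (int a = 0; a < 3; ++a) fint(3 * nd + a) += fe(i, a);
    }
    if (want_tangent) {
      // characteristic element length for the FD step
      double lch = std::sqrt(accu(square(Xe.row(1) - Xe.row(0))));
      double h = 1e-6 * (lch > 0 ? lch : 1.0);
      for (int j = 0; j < ndof; ++j) {
        bool okp = true;
        if (etype == 0) {
          uetp = uet;
          uetp(j % 3, j / 3) += h;
          hex_residual(href, uetp, mu(e), kappa(e), lambda(e), model(e), hfep, okp);
          if (!okp) { allok = false; break; }
          uetp(j % 3, j / 3) -= 2 * h;
          hex_residual(href, uetp, mu(e), kappa(e), lambda(e), model(e), hfem, okp);
          if (!okp) { allok = false; break; }
          fep = hfep; fem = hfem;
        } else {
          uep = ue;
          uep(j / 3, j % 3) += h;
          tri_residual(tref, Xe, uep, mu(e), thickness(e), fep, okp);
          if (!okp) { allok = false; break; }
          uep(j / 3, j % 3) -= 2 * h;
          tri_residual(tref, Xe, uep, mu(e), thickness(e), fem, okp);
          if (!okp) { allok = false; break; }
        }
        int gj = 3 * (elems(e, j / 3) - 1) + (j % 3);
        for (int i = 0; i < ndof; ++i) {
          double kij = (fep(i / 3, i % 3) - fem(i / 3, i % 3)) / (2 * h);
          if (kij != 0.0) {
            int gi = 3 * (elems(e, i / 3) - 1) + (i % 3);
            if (dense) Kd(gi, gj) += kij;
            else { ti.push_back(gi + 1); tj.push_back(gj + 1); tv.push_back(kij); }
          }
        }
      }
      if (!allok) break;
    }
  }
  if (want_tangent && dense) {
    return Rcpp::List::create(
      Rcpp::Named("f") = fint, Rcpp::Named("K") = Kd,
      Rcpp::Named("ok") = allok);
  }
  return Rcpp::List::create(
    Rcpp::Named("f") = fint,
    Rcpp::Named("i") = ti, Rcpp::Named("j") = tj, Rcpp::Named("v") = tv,
    Rcpp::Named("ok") = allok);
}

// follower pressure nodal forces on one face (quad: 2x2 Gauss, tri: exact)
static void face_force(const mat &xe, double p, mat &fe) {
  int npf = xe.n_rows;
  fe.zeros(npf, 3);
  if (npf == 3) {
    vec g1 = (xe.row(1) - xe.row(0)).t();
    vec g2 = (xe.row(2) - xe.row(0)).t();
    vec nA = 0.5 * cross(g1, g2); // normal * area
    for (int i = 0; i < 3; ++i) fe.row(i) = (p / 3.0) * nA.t();
  } else {
    static const double gp[2] = {-GP, GP};
    const double sx[4] = {-1, 1, 1, -1};
    const double sy[4] = {-1, -1, 1, 1};
    for (int a = 0; a < 2; ++a) for (int b = 0; b < 2; ++b) {
      double xi = gp[a], eta = gp[b];
      vec N(4), dNxi(4), dNeta(4);
      for (int i = 0; i < 4; ++i) {
        N(i) = 0.25 * (1 + sx[i] * xi) * (1 + sy[i] * eta);
        dNxi(i) = 0.25 * sx[i] * (1 + sy[i] * eta);
        dNeta(i) = 0.25 * sy[i] * (1 + sx[i] * xi);
      }
      vec xxi = xe.t() * dNxi, xeta = xe.t() * dNeta;
      vec nrm = cross(xxi, xeta);
      for (int i = 0; i < 4; ++i) fe.row(i) += p * N(i) * nrm.t();
    }
  }
}

// [[Rcpp::export]]
Rcpp::List assemble_pressure_cpp(const arma::mat &nodes, const arma::imat &faces,
                                 const arma::vec &u, double p, bool want_tangent,
                                 bool dense = false) {
  int nn = nodes.n_rows, nf = faces.n_rows;
  int npf = faces.n_cols;
  int ndof = npf * 3;
  vec fext(3 * nn, fill::zeros);
  mat Kd;
  if (want_tangent && dense) Kd.zeros(3 * nn, 3 * nn);
  std::vector<double> ti, tj, tv;
  mat xe(npf, 3), fe(npf, 3), fep(npf, 3), xep(npf, 3);
  for (int e = 0; e < nf; ++e) {
    for (int i = 0; i < npf; ++i) {
      int nd = faces(e, i) - 1;
      for (int a = 0; a < 3; ++a) xe(i, a) = nodes(nd, a) + u(3 * nd + a);
    }
    face_force(xe, p, fe);
    for (int i = 0; i < npf; ++i) {
      int nd = faces(e, i) - 1;
      for (int a = 0; a < 3; ++a) fext(3 * nd + a) += fe(i, a);
    }
    if (want_tangent) {
      double lch = std::sqrt(accu(square(xe.row(1) - xe.row(0))));
      double h = 1e-6 * (lch > 0 ? lch : 1.0);
      for (int j = 0; j < ndof; ++j) {
        xep = xe;
        xep(j / 3, j % 3) += h;
        face_force(xep, p, fep);
        int gj = 3 * (faces(e, j / 3) - 1) + (j % 3);
        for (int i = 0; i < ndof; ++i) {
          double kij = (fep(i / 3, i % 3) - fe(i / 3, i % 3)) / h;
          if (kij != 0.0) {
            int gi = 3 * (faces(e, i / 3) - 1) + (i % 3);
            if (dense) Kd(gi, gj) += kij;
            else { ti.push_back(gi + 1); tj.push_back(gj + 1); tv.push_back(kij); }
          }
        }
      }
    }
  }
  if (want_tangent && dense) {
    return Rcpp::List::create(Rcpp::Named("f") = fext, Rcpp::Named("K") = Kd);
  }
  return Rcpp::List::create(
    Rcpp::Named("f") = fext,
    Rcpp::Named("i") = ti, Rcpp::Named("j") = tj, Rcpp::Named("v") = tv);
}

// diagonal (lumped) mass per dof; rho per element (solids: mass/volume,
// membranes: mass/volume times thickness gives mass/area)
// [[Rcpp::export]]
arma::vec lumped_mass_cpp(const arma::mat &nodes, const arma::imat &elems,
                          const arma::vec &rho, const arma::vec &thickness,
                          int etype) {
  int nn = nodes.n_rows, ne = elems.n_rows;
  vec m(3 * nn, fill::zeros);
  if (etype == 0) {
    vec vols = hex_volumes_cpp(nodes, elems);
    for (int e = 0; e < ne; ++e) {
      double mnode = rho(e) * vols(e) / 8.0;
      for (int i = 0; i < 8; ++i) {
        int nd = elems(e, i) - 1;
        for (int a = 0; a < 3; ++a) m(3 * nd + a) += mnode;
      }
    }
  } else {
    for (int e = 0; e < ne; ++e) {
      vec a1 = (nodes.row(elems(e, 1) - 1) - nodes.row(elems(e, 0) - 1)).t();
      vec a2 = (nodes.row(elems(e, 2) - 1) - nodes.row(elems(e, 0) - 1)).t();
      double A = 0.5 * norm(cross(a1, a2));
      double mnode = rho(e) * thickness(e) * A / 3.0;
      for (int i = 0; i < 3; ++i) {
        int nd = elems(e, i) - 1;
        for (int a = 0; a < 3; ++a) m(3 * nd + a) += mnode;
      }
    }
  }
  return m;
}
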
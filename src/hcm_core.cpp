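// Core finite-element kernels for the homogenized constrained mixture model.
//
// Total-Lagrangian trilinear hexahedra, 2x2x2 Gauss quadrature for the
// deviatoric/fiber response and a single central point for the volumetric
// term of the matrix constituent (selective reduced integration, which
// avoids locking at the near-incompressible bulk ratios used here).
//
// Units: lengths mm, stresses kPa, densities kg/m^3, moduli J/kg.
// Density-weighted moduli (rho * mu etc.) are premultiplied on the R side
// and passed here in kPa.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::mat::fixed<3, 3> mat3;
typedef arma::mat::fixed<6, 6> mat66;

// Voigt order (11, 22, 33, 12, 23, 13)
static const int VI[6] = {0, 1, 2, 0, 1, 0};
static const int VJ[6] = {0, 1, 2, 1, 2, 2};

static inline void sym2v(const mat3 &A, double v[6]) {
  v[0] = A(0, 0); v[1] = A(1, 1); v[2] = A(2, 2);
  v[3] = A(0, 1); v[4] = A(1, 2); v[5] = A(0, 2);
}

// D += c * v(A) v(B)^T
static inline void addDyad(mat66 &D, const double a[6], const double b[6],
                           double c) {
  for (int p = 0; p < 6; ++p)
    for (int q = 0; q < 6; ++q) D(p, q) += c * a[p] * b[q];
}

// D += c * (A (.) A)_sym, i.e. c/2 (A_ik A_jl + A_il A_jk)
static inline void addSymProd(mat66 &D, const mat3 &A, double c) {
  for (int p = 0; p < 6; ++p) {
    int i = VI[p], j = VJ[p];
    for (int q = 0; q < 6; ++q) {
      int k = VI[q], l = VJ[q];
      D(p, q) += 0.5 * c * (A(i, k) * A(j, l) + A(i, l) * A(j, k));
    }
  }
}

// trilinear hex, VTK cell-12 node ordering
static const double HS[8][3] = {{-1, -1, -1}, {1, -1, -1}, {1, 1, -1},
                                {-1, 1, -1},  {-1, -1, 1}, {1, -1, 1},
                                {1, 1, 1},    {-1, 1, 1}};

static inline void hexShape(double xi, double eta, double ze, double N[8],
                            double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    double sx = HS[a][0], sy = HS[a][1], sz = HS[a][2];
    N[a] = 0.125 * (1 + xi * sx) * (1 + eta * sy) * (1 + ze * sz);
    dN[a][0] = 0.125 * sx * (1 + eta * sy) * (1 + ze * sz);
    dN[a][1] = 0.125 * sy * (1 + xi * sx) * (1 + ze * sz);
    dN[a][2] = 0.125 * sz * (1 + xi * sx) * (1 + eta * sy);
  }
}

// Precompute reference shape-function gradients, jacobians and quadrature
// point coordinates for all elements.
// [[Rcpp::export]]
List hexPrecompute(const NumericMatrix coords, const IntegerMatrix elems) {
  const int ne = elems.nrow();
  const double gp = 1.0 / std::sqrt(3.0);
  NumericVector dNdX(ne * 8 * 24);        // [e][gp][a][i]
  NumericMatrix detJw(ne, 8);
  NumericVector dNdX0(ne * 24);
  NumericVector detJ0(ne);
  NumericMatrix qpXYZ(ne * 8, 3);

  double N[8], dN[8][3];
  for (int e = 0; e < ne; ++e) {
    arma::mat Xe(8, 3);
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a);
      for (int i = 0; i < 3; ++i) Xe(a, i) = coords(n, i);
    }
    for (int g = 0; g < 9; ++g) {  // 8 corner gps + center
      double xi, eta, ze;
      if (g < 8) { xi = gp * HS[g][0]; eta = gp * HS[g][1]; ze = gp * HS[g][2]; }
      else { xi = eta = ze = 0.0; }
      hexShape(xi, eta, ze, N, dN);
      mat3 Jm; Jm.zeros();
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Jm(i, j) += Xe(a, i) * dN[a][j];
      double dJ = arma::det(Jm);
      if (dJ <= 0) stop("non-positive Jacobian in element %d", e + 1);
      mat3 Jinv = arma::inv(Jm);
      if (g < 8) {
        detJw(e, g) = dJ;  // weight 1 per gauss point
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            double s = 0;
            for (int k = 0; k < 3; ++k) s += dN[a][k] * Jinv(k, i);
            dNdX[((e * 8 + g) * 8 + a) * 3 + i] = s;
          }
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += N[a] * Xe(a, i);
          qpXYZ(e * 8 + g, i) = s;
        }
      } else {
        detJ0[e] = dJ * 8.0;  // 1-point rule weight
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            double s = 0;
            for (int k = 0; k < 3; ++k) s += dN[a][k] * Jinv(k, i);
            dNdX0[(e * 8 + a) * 3 + i] = s;
          }
      }
    }
  }
  return List::create(_["dNdX"] = dNdX, _["detJw"] = detJw,
                      _["dNdX0"] = dNdX0, _["detJ0"] = detJ0,
                      _["qp_coords"] = qpXYZ);
}

struct QPState {
  const double *H6, *g, *rmu, *rkap;
  const double *A, *K1, *K2, *Lr2, *Act;
  const int *Tens;
  int nqp, nf;
};

// Mixture PK2 stress and tangent at one quadrature point.
// dev: matrix-deviatoric + fibers + active; vol: matrix volumetric term.
static void evalMixture(const QPState &qs, int qp, const mat3 &C,
                        const mat3 &Cinv, double J, bool dev, bool vol,
                        bool wantK, mat3 &S, mat66 &D) {
  S.zeros();
  if (wantK) D.zeros();
  const int nqp = qs.nqp;
  double g = qs.g[qp];
  double Je = J * g;
  if (Je <= 0) stop("non-positive elastic volume ratio");
  double vCi[6]; sym2v(Cinv, vCi);

  if (dev) {
    mat3 H;
    H(0, 0) = qs.H6[qp]; H(1, 1) = qs.H6[qp + nqp]; H(2, 2) = qs.H6[qp + 2 * nqp];
    H(0, 1) = H(1, 0) = qs.H6[qp + 3 * nqp];
    H(1, 2) = H(2, 1) = qs.H6[qp + 4 * nqp];
    H(0, 2) = H(2, 0) = qs.H6[qp + 5 * nqp];
    double rmu = qs.rmu[qp];
    if (rmu != 0) {
      double I1e = arma::accu(H % C);
      double f = rmu * std::pow(Je, -2.0 / 3.0);
      S += f * H - (f * I1e / 3.0) * Cinv;
      if (wantK) {
        double vH[6]; sym2v(H, vH);
        addDyad(D, vH, vCi, -2.0 * f / 3.0);
        addDyad(D, vCi, vH, -2.0 * f / 3.0);
        addDyad(D, vCi, vCi, 2.0 * f * I1e / 9.0);
        addSymProd(D, Cinv, 2.0 * f * I1e / 3.0);
      }
    }
    for (int fb = 0; fb < qs.nf; ++fb) {
      int off = qp + fb * nqp;
      double a0[3] = {qs.A[qp + (3 * fb) * nqp], qs.A[qp + (3 * fb + 1) * nqp],
                      qs.A[qp + (3 * fb + 2) * nqp]};
      double lam2 = 0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) lam2 += a0[i] * C(i, j) * a0[j];
      mat3 M;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) M(i, j) = a0[i] * a0[j];
      double vM[6]; sym2v(M, vM);
      double c1 = qs.K1[off];
      if (c1 != 0) {
        double lr2 = qs.Lr2[off];
        double x = lam2 / lr2;
        bool skip = qs.Tens[fb] && x < 1.0;
        if (!skip) {
          double xm = x - 1.0, k2 = qs.K2[off];
          if (xm > 10.0) stop("fiber stretch out of range (lambda_e^2-1 > 10)");
          double E = std::exp(k2 * xm * xm);
          S += (c1 * xm * E / lr2) * M;
          if (wantK)
            addDyad(D, vM, vM,
                    2.0 * c1 * E * (1.0 + 2.0 * k2 * xm * xm) / (lr2 * lr2));
        }
      }
      double sa = qs.Act[off];
      if (sa != 0) {
        S += (sa * J / lam2) * M;
        if (wantK) {
          addDyad(D, vM, vCi, sa * J / lam2);
          addDyad(D, vM, vM, -2.0 * sa * J / (lam2 * lam2));
        }
      }
    }
  }
  if (vol) {
    double rkap = qs.rkap[qp];
    if (rkap != 0) {
      double q1 = rkap * Je * (Je - 1.0);
      S += q1 * Cinv;
      if (wantK) {
        addDyad(D, vCi, vCi, rkap * Je * (2.0 * Je - 1.0));
        addSymProd(D, Cinv, -2.0 * q1);
      }
    }
  }
}

static inline void defGrad(const double *dN, const double ue[8][3], mat3 &F) {
  F.eye();
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) F(i, j) += ue[a][i] * dN[a * 3 + j];
}

// Assemble internal forces, follower pressure loads and (optionally) the
// consistent tangent into a preallocated CSC value vector.
// [[Rcpp::export]]
List feAssemble(const NumericMatrix coords, const IntegerMatrix elems,
                const NumericVector dNdX, const NumericMatrix detJw,
                const NumericVector dNdX0, const NumericVector detJ0,
                const NumericVector u, const NumericMatrix H6,
                const NumericVector gdet, const NumericVector rmu,
                const NumericVector rkap, const NumericMatrix fibA,
                const NumericMatrix fibK1, const NumericMatrix fibK2,
                const NumericMatrix fibLr2, const NumericMatrix fibAct,
                const IntegerVector fibTens, const IntegerMatrix facets,
                double pres, const IntegerVector xmapE,
                const IntegerVector xmapF, int nnz, bool wantK) {
  const int ne = elems.nrow(), nn = coords.nrow();
  const int nf = fibK1.ncol();
  QPState qs;
  qs.H6 = H6.begin(); qs.g = gdet.begin(); qs.rmu = rmu.begin();
  qs.rkap = rkap.begin(); qs.A = fibA.begin(); qs.K1 = fibK1.begin();
  qs.K2 = fibK2.begin(); qs.Lr2 = fibLr2.begin(); qs.Act = fibAct.begin();
  qs.Tens = fibTens.begin(); qs.nqp = ne * 8; qs.nf = nf;

  NumericVector fint(3 * nn), fext(3 * nn);
  NumericVector xvals(wantK ? nnz : 0);
  double *xv = xvals.begin();
  const double *pu = u.begin();

  mat3 F, C, Cinv, S, P;
  mat66 D;
  arma::mat B(6, 24), Ke(24, 24), DB(6, 24);

  for (int e = 0; e < ne; ++e) {
    double ue[8][3];
    int nd[8];
    for (int a = 0; a < 8; ++a) {
      nd[a] = elems(e, a);
      for (int i = 0; i < 3; ++i) ue[a][i] = pu[3 * nd[a] + i];
    }
    double fe[24] = {0};
    if (wantK) Ke.zeros();

    for (int g = 0; g < 9; ++g) {
      const double *dN;
      double w;
      bool dev, vol;
      int qp = e * 8 + (g < 8 ? g : 0);
      if (g < 8) {
        dN = &dNdX[(e * 8 + g) * 24];
        w = detJw(e, g);
        dev = true; vol = false;
      } else {
        dN = &dNdX0[e * 24];
        w = detJ0[e];
        dev = false; vol = true;
      }
      defGrad(dN, ue, F);
      double J = arma::det(F);
      if (J <= 0) stop("element inversion");
      C = F.t() * F;
      Cinv = arma::inv_sympd(C);
      evalMixture(qs, qp, C, Cinv, J, dev, vol, wantK, S, D);
      P = F * S;
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += P(i, j) * dN[a * 3 + j];
          fe[3 * a + i] += w * s;
        }
      if (wantK) {
        for (int a = 0; a < 8; ++a) {
          const double d0 = dN[a * 3 + 0], d1 = dN[a * 3 + 1], d2 = dN[a * 3 + 2];
          for (int i = 0; i < 3; ++i) {
            int c = 3 * a + i;
            B(0, c) = F(i, 0) * d0;
            B(1, c) = F(i, 1) * d1;
            B(2, c) = F(i, 2) * d2;
            B(3, c) = F(i, 0) * d1 + F(i, 1) * d0;
            B(4, c) = F(i, 1) * d2 + F(i, 2) * d1;
            B(5, c) = F(i, 0) * d2 + F(i, 2) * d0;
          }
        }
        DB = D * B;
        Ke += w * (B.t() * DB);
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double gab = 0;
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                gab += dN[a * 3 + i] * S(i, j) * dN[b * 3 + j];
            gab *= w;
            for (int i = 0; i < 3; ++i) Ke(3 * a + i, 3 * b + i) += gab;
          }
      }
    }
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) fint[3 * nd[a] + i] += fe[3 * a + i];
    if (wantK) {
      const int *xm = &xmapE[e * 576];
      for (int p = 0; p < 24; ++p)
        for (int q = 0; q < 24; ++q) xv[xm[p * 24 + q]] += Ke(p, q);
    }
  }

  // follower pressure on luminal facets
  if (pres != 0.0 && facets.nrow() > 0) {
    const double gq = 1.0 / std::sqrt(3.0);
    const double QS[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
    arma::mat Kf(12, 12);
    for (int f = 0; f < facets.nrow(); ++f) {
      int nd[4];
      double xe[4][3];
      for (int a = 0; a < 4; ++a) {
        nd[a] = facets(f, a);
        for (int i = 0; i < 3; ++i)
          xe[a][i] = coords(nd[a], i) + pu[3 * nd[a] + i];
      }
      double fe[12] = {0};
      if (wantK) Kf.zeros();
      for (int g = 0; g < 4; ++g) {
        double xi = gq * QS[g][0], eta = gq * QS[g][1];
        double N[4], dNxi[4], dNeta[4];
        for (int a = 0; a < 4; ++a) {
          N[a] = 0.25 * (1 + xi * QS[a][0]) * (1 + eta * QS[a][1]);
          dNxi[a] = 0.25 * QS[a][0] * (1 + eta * QS[a][1]);
          dNeta[a] = 0.25 * QS[a][1] * (1 + xi * QS[a][0]);
        }
        double xxi[3] = {0, 0, 0}, xeta[3] = {0, 0, 0};
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i) {
            xxi[i] += dNxi[a] * xe[a][i];
            xeta[i] += dNeta[a] * xe[a][i];
          }
        double cr[3] = {xxi[1] * xeta[2] - xxi[2] * xeta[1],
                        xxi[2] * xeta[0] - xxi[0] * xeta[2],
                        xxi[0] * xeta[1] - xxi[1] * xeta[0]};
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i) fe[3 * a + i] += pres * N[a] * cr[i];
        if (wantK) {
          // d(x_xi x x_eta) = -skew(x_eta) dNxi_b + skew(x_xi) dNeta_b
          for (int b = 0; b < 4; ++b) {
            mat3 Mb;
            Mb(0, 0) = 0; Mb(1, 1) = 0; Mb(2, 2) = 0;
            Mb(0, 1) = dNxi[b] * xeta[2] - dNeta[b] * xxi[2];
            Mb(0, 2) = -dNxi[b] * xeta[1] + dNeta[b] * xxi[1];
            Mb(1, 0) = -dNxi[b] * xeta[2] + dNeta[b] * xxi[2];
            Mb(1, 2) = dNxi[b] * xeta[0] - dNeta[b] * xxi[0];
            Mb(2, 0) = dNxi[b] * xeta[1] - dNeta[b] * xxi[1];
            Mb(2, 1) = -dNxi[b] * xeta[0] + dNeta[b] * xxi[0];
            for (int a = 0; a < 4; ++a)
              for (int i = 0; i < 3; ++i)
                for (int j = 0; j < 3; ++j)
                  Kf(3 * a + i, 3 * b + j) += pres * N[a] * Mb(i, j);
          }
        }
      }
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) fext[3 * nd[a] + i] += fe[3 * a + i];
      if (wantK) {
        const int *xm = &xmapF[f * 144];
        for (int p = 0; p < 12; ++p)
          for (int q = 0; q < 12; ++q) xv[xm[p * 12 + q]] -= Kf(p, q);
      }
    }
  }
  return List::create(_["fint"] = fint, _["fext"] = fext, _["xvals"] = xvals);
}

// Per-quadrature-point kinematics and stresses for output and for the
// growth/remodeling update: deformation gradient, mixture Cauchy stress
// (Voigt), fiber squared elastic stretches and mass-specific fiber stresses.
// [[Rcpp::export]]
List qpFields(const NumericMatrix coords, const IntegerMatrix elems,
              const NumericVector dNdX, const NumericVector dNdX0,
              const NumericVector u,
              const NumericMatrix H6, const NumericVector gdet,
              const NumericVector rmu, const NumericVector rkap,
              const NumericMatrix fibA, const NumericMatrix fibK1,
              const NumericMatrix fibK2, const NumericMatrix fibLr2,
              const NumericMatrix fibAct, const IntegerVector fibTens,
              const NumericMatrix fibRho, const NumericMatrix fibK1spec) {
  const int ne = elems.nrow();
  const int nf = fibK1.ncol();
  const int nqp = ne * 8;
  QPState qs;
  qs.H6 = H6.begin(); qs.g = gdet.begin(); qs.rmu = rmu.begin();
  qs.rkap = rkap.begin(); qs.A = fibA.begin(); qs.K1 = fibK1.begin();
  qs.K2 = fibK2.begin(); qs.Lr2 = fibLr2.begin(); qs.Act = fibAct.begin();
  qs.Tens = fibTens.begin(); qs.nqp = nqp; qs.nf = nf;
  const double *pu = u.begin();

  NumericVector Jv(nqp);
  NumericMatrix Fout(nqp, 9), cauchy(nqp, 6), fibX(nqp, nf), fibS(nqp, nf);
  mat3 F, C, Cinv, S, sig, sigv;
  mat66 D;
  for (int e = 0; e < ne; ++e) {
    double ue[8][3];
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a);
      for (int i = 0; i < 3; ++i) ue[a][i] = pu[3 * n + i];
    }
    // volumetric (matrix) Cauchy contribution at the element centre, where
    // the selectively reduced volumetric term is integrated
    defGrad(&dNdX0[e * 24], ue, F);
    {
      double Jc = arma::det(F);
      if (Jc <= 0) stop("element inversion");
      C = F.t() * F;
      Cinv = arma::inv_sympd(C);
      evalMixture(qs, e * 8, C, Cinv, Jc, false, true, false, S, D);
      sigv = (F * S * F.t()) / Jc;
    }
    for (int g = 0; g < 8; ++g) {
      int qp = e * 8 + g;
      const double *dN = &dNdX[qp * 24];
      defGrad(dN, ue, F);
      double J = arma::det(F);
      if (J <= 0) stop("element inversion");
      C = F.t() * F;
      Cinv = arma::inv_sympd(C);
      evalMixture(qs, qp, C, Cinv, J, true, false, false, S, D);
      sig = (F * S * F.t()) / J + sigv;
      Jv[qp] = J;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) Fout(qp, 3 * i + j) = F(i, j);
      cauchy(qp, 0) = sig(0, 0); cauchy(qp, 1) = sig(1, 1);
      cauchy(qp, 2) = sig(2, 2); cauchy(qp, 3) = sig(0, 1);
      cauchy(qp, 4) = sig(1, 2); cauchy(qp, 5) = sig(0, 2);
      for (int fb = 0; fb < nf; ++fb) {
        int off = qp + fb * nqp;
        double a0[3] = {qs.A[qp + (3 * fb) * nqp],
                        qs.A[qp + (3 * fb + 1) * nqp],
                        qs.A[qp + (3 * fb + 2) * nqp]};
        double lam2 = 0;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) lam2 += a0[i] * C(i, j) * a0[j];
        double lr2 = qs.Lr2[off];
        double x = lam2 / lr2;
        fibX(qp, fb) = x;
        // mass-specific fiber-direction Cauchy stress (per unit reference
        // mass, scaled by the mixture volume ratio): the homeostatic
        // driver of mass turnover
        double s = 0;
        if (!(qs.Tens[fb] && x < 1.0)) {
          double xm = x - 1.0, k2 = qs.K2[off];
          double E = std::exp(std::min(k2 * xm * xm, 700.0));
          s = fibK1spec(qp, fb) * xm * E * x / J;
        }
        double rhop = fibRho(qp, fb);
        if (qs.Act[off] != 0 && rhop > 0) s += qs.Act[off] / rhop;
        fibS(qp, fb) = s;
      }
    }
  }
  return List::create(_["J"] = Jv, _["F"] = Fout, _["cauchy"] = cauchy,
                      _["fib_x"] = fibX, _["fib_s"] = fibS);
}

// Mixture PK2 stress and Voigt tangent at a single material point, given
// the right Cauchy-Green tensor and the same per-point state arrays used in
// assembly (with nqp = 1).
// [[Rcpp::export]]
List mixPoint(const NumericMatrix Cm, const NumericMatrix H6,
              const NumericVector gdet, const NumericVector rmu,
              const NumericVector rkap, const NumericMatrix fibA,
              const NumericMatrix fibK1, const NumericMatrix fibK2,
              const NumericMatrix fibLr2, const NumericMatrix fibAct,
              const IntegerVector fibTens, bool wantK) {
  QPState qs;
  qs.H6 = H6.begin(); qs.g = gdet.begin(); qs.rmu = rmu.begin();
  qs.rkap = rkap.begin(); qs.A = fibA.begin(); qs.K1 = fibK1.begin();
  qs.K2 = fibK2.begin(); qs.Lr2 = fibLr2.begin(); qs.Act = fibAct.begin();
  qs.Tens = fibTens.begin(); qs.nqp = 1; qs.nf = fibK1.ncol();
  mat3 C, Cinv, S;
  mat66 D;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) C(i, j) = Cm(i, j);
  double J = std::sqrt(arma::det(C));
  Cinv = arma::inv_sympd(C);
  evalMixture(qs, 0, C, Cinv, J, true, true, wantK, S, D);
  NumericMatrix Sout(3, 3), Dout(6, 6);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Sout(i, j) = S(i, j);
  if (wantK)
    for (int p = 0; p < 6; ++p)
      for (int q = 0; q < 6; ++q) Dout(p, q) = D(p, q);
  return List::create(_["S"] = Sout, _["D"] = Dout);
}

// Positions of (i, j) entries (0-based) in a dgCMatrix given its slots.
// [[Rcpp::export]]
IntegerVector cscIndex(const IntegerVector Kp, const IntegerVector Ki,
                       const IntegerVector ii, const IntegerVector jj) {
  const int m = ii.size();
  IntegerVector out(m);
  for (int q = 0; q < m; ++q) {
    int col = jj[q], row = ii[q];
    int lo = Kp[col], hi = Kp[col + 1] - 1, pos = -1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (Ki[mid] == row) { pos = mid; break; }
      if (Ki[mid] < row) lo = mid + 1; else hi = mid - 1;
    }
    if (pos < 0) stop("entry not present in sparsity pattern");
    out[q] = pos;
  }
  return out;
}
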
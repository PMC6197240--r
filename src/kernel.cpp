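// Biphasic (u-p) total-Lagrangian element kernel for 4-node quadrilaterals.
//
// Each node carries (ux, uy, p) where p is the chemical potential of water
// (the FE pressure unknown, MPa); the Donnan swelling pressure and chemical
// expansion stress are evaluated constitutively from the local fixed charge
// density and enter the total Cauchy stress together with p.
//
// Units: mm, N, s, MPa, mEq/ml.  Axisymmetric volumes are per radian.
//
// The element tangent is a forward finite difference of the analytic
// residual over the 12 element dofs; with the residual tolerance used by the
// Newton driver (1e-6 relative) this is indistinguishable from an exact
// consistent tangent.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.5773502691896258;  // 1/sqrt(3)

struct Pars {
  double Ef, Knf, Gnf, k, cext, RT, phi_int, phi_ext, gam, a0, kappa, alpha;
};

static inline void shape(double xi, double eta, double *N, double dN[4][2]) {
  static const double xs[4] = {-1, 1, 1, -1};
  static const double ys[4] = {-1, -1, 1, 1};
  for (int a = 0; a < 4; a++) {
    N[a] = 0.25 * (1 + xs[a] * xi) * (1 + ys[a] * eta);
    dN[a][0] = 0.25 * xs[a] * (1 + ys[a] * eta);
    dN[a][1] = 0.25 * ys[a] * (1 + xs[a] * xi);
  }
}

// Donnan osmotic pressure (MPa) at current FCD c (mEq/ml per current fluid
// volume); ideal/non-ideal coefficients and the RT unit constant in p.
static inline double donnan(double c, const Pars &p) {
  double root = std::sqrt(c * c + 4.0 * p.gam * p.gam * p.cext * p.cext);
  return p.phi_int * p.RT * root - 2.0 * p.phi_ext * p.RT * p.cext;
}

// Chemical expansion stress (MPa); mobile anion concentration from ideal
// Donnan equilibrium.
static inline double chem_exp(double c, const Pars &p) {
  if (p.a0 <= 0.0 || c <= 0.0) return 0.0;
  double root = std::sqrt(c * c + 4.0 * p.gam * p.gam * p.cext * p.cext);
  double cm = 0.5 * (root - c);
  return p.a0 * c * std::exp(-p.kappa * p.gam * std::sqrt(cm * (cm + c)));
}

// Per-Gauss-point state needed by the element residual and postprocessing.
struct GpOut {
  double w;            // integration weight (incl. detJ and r for axisym)
  double N[4];
  double dNdX[4][2];
  double F2[2][2];     // in-plane deformation gradient
  double lz;           // out-of-plane stretch
  double J;            // total volume ratio
  double Jold;
  double pgp, pgp_old;
  double c;            // current FCD
  double dpi, Tc;
  double sig[4];       // total Cauchy: xx, yy, xy, zz
  double r0;           // reference radius (axisym)
  double gradp[2];     // material gradient of p
  bool ok;
};

// Evaluate kinematics + constitutive response at one Gauss point.
// Xe: 4x2 reference coords; de: 12 dofs (ux,uy,p per node); fib: pointer to
// ndir rows of (dx,dy,dz,weight) for this gp.
static bool gp_eval(int igp, const double Xe[4][2], const double de[12],
                    const double de_old[12], double cfcd0, double nfl0,
                    const double *fib, int ndir, const Pars &pars,
                    int axisym, double swell, GpOut &o) {
  static const double xig[4] = {-GP, GP, GP, -GP};
  static const double etg[4] = {-GP, -GP, GP, GP};
  double N[4], dN[4][2];
  shape(xig[igp], etg[igp], N, dN);

  // reference Jacobian
  double Jm[2][2] = {{0, 0}, {0, 0}};
  for (int a = 0; a < 4; a++) {
    Jm[0][0] += Xe[a][0] * dN[a][0]; Jm[0][1] += Xe[a][0] * dN[a][1];
    Jm[1][0] += Xe[a][1] * dN[a][0]; Jm[1][1] += Xe[a][1] * dN[a][1];
  }
  double detJm = Jm[0][0] * Jm[1][1] - Jm[0][1] * Jm[1][0];
  if (detJm <= 0.0) return false;
  double Ji[2][2] = {{ Jm[1][1] / detJm, -Jm[0][1] / detJm},
                     {-Jm[1][0] / detJm,  Jm[0][0] / detJm}};
  for (int a = 0; a < 4; a++) {
    o.dNdX[a][0] = dN[a][0] * Ji[0][0] + dN[a][1] * Ji[1][0];
    o.dNdX[a][1] = dN[a][0] * Ji[0][1] + dN[a][1] * Ji[1][1];
    o.N[a] = N[a];
  }

  double r0 = 0.0;
  for (int a = 0; a < 4; a++) r0 += N[a] * Xe[a][0];
  o.r0 = r0;
  o.w = detJm * (axisym ? r0 : 1.0);  // unit gauss weights (2x2 rule)

  // deformation gradient, current and old
  double F2[2][2] = {{1, 0}, {0, 1}}, F2o[2][2] = {{1, 0}, {0, 1}};
  double ur = 0.0, ur_old = 0.0;
  for (int a = 0; a < 4; a++) {
    double ux = de[3 * a], uy = de[3 * a + 1];
    double uxo = de_old[3 * a], uyo = de_old[3 * a + 1];
    F2[0][0] += ux * o.dNdX[a][0]; F2[0][1] += ux * o.dNdX[a][1];
    F2[1][0] += uy * o.dNdX[a][0]; F2[1][1] += uy * o.dNdX[a][1];
    F2o[0][0] += uxo * o.dNdX[a][0]; F2o[0][1] += uxo * o.dNdX[a][1];
    F2o[1][0] += uyo * o.dNdX[a][0]; F2o[1][1] += uyo * o.dNdX[a][1];
    ur += N[a] * ux; ur_old += N[a] * uxo;
  }
  double J2 = F2[0][0] * F2[1][1] - F2[0][1] * F2[1][0];
  double J2o = F2o[0][0] * F2o[1][1] - F2o[0][1] * F2o[1][0];
  if (J2 <= 0.0) return false;
  double lz = 1.0, lzo = 1.0;
  if (axisym) {
    if (r0 <= 0.0) return false;
    lz = 1.0 + ur / r0;
    lzo = 1.0 + ur_old / r0;
    if (lz <= 0.0) return false;
  }
  double J = J2 * lz, Jold = J2o * lzo;
  for (int i = 0; i < 2; i++)
    for (int j = 0; j < 2; j++) o.F2[i][j] = F2[i][j];
  o.lz = lz; o.J = J; o.Jold = Jold;

  // pressure dof interpolation and material gradient
  o.pgp = 0.0; o.pgp_old = 0.0; o.gradp[0] = 0.0; o.gradp[1] = 0.0;
  for (int a = 0; a < 4; a++) {
    o.pgp += N[a] * de[3 * a + 2];
    o.pgp_old += N[a] * de_old[3 * a + 2];
    o.gradp[0] += o.dNdX[a][0] * de[3 * a + 2];
    o.gradp[1] += o.dNdX[a][1] * de[3 * a + 2];
  }

  // current FCD: reference FCD defined per unit reference fluid volume,
  // rescaled by the current fluid volume J - n_s0 (incompressible solid)
  double ns0 = 1.0 - nfl0;
  double Jfl = J - ns0;
  if (Jfl < 1e-6) Jfl = 1e-6;
  double c = cfcd0 * nfl0 / Jfl;
  if (c < 0.0) c = 0.0;
  o.c = c;
  o.dpi = swell * donnan(c, pars);
  o.Tc = swell * chem_exp(c, pars);

  // non-fibrillar neo-Hookean Cauchy stress
  double lnJ = std::log(J);
  double J23 = std::pow(J, 2.0 / 3.0);
  double B2[2][2] = {
    {F2[0][0] * F2[0][0] + F2[0][1] * F2[0][1],
     F2[0][0] * F2[1][0] + F2[0][1] * F2[1][1]},
    {F2[1][0] * F2[0][0] + F2[1][1] * F2[0][1],
     F2[1][0] * F2[1][0] + F2[1][1] * F2[1][1]}};
  double sxx = pars.Knf * lnJ / J + pars.Gnf / J * (B2[0][0] - J23);
  double syy = pars.Knf * lnJ / J + pars.Gnf / J * (B2[1][1] - J23);
  double sxy = pars.Gnf / J * B2[0][1];
  double szz = pars.Knf * lnJ / J + pars.Gnf / J * (lz * lz - J23);

  // fibril network: tension-only, logarithmic fibril strain
  for (int i = 0; i < ndir; i++) {
    const double *f = fib + 4 * i;
    double vx = F2[0][0] * f[0] + F2[0][1] * f[1];
    double vy = F2[1][0] * f[0] + F2[1][1] * f[1];
    double vz = lz * f[2];
    double lam2 = vx * vx + vy * vy + vz * vz;
    if (lam2 <= 1.0) continue;           // log strain <= 0: no stress
    double lam = std::sqrt(lam2);
    double s = f[3] * pars.Ef * std::log(lam) / lam2;  // sigma/lam^2
    sxx += s * vx * vx;
    syy += s * vy * vy;
    sxy += s * vx * vy;
    szz += s * vz * vz;
  }

  double ph = o.dpi + o.Tc + o.pgp;
  o.sig[0] = sxx - ph;
  o.sig[1] = syy - ph;
  o.sig[2] = sxy;
  o.sig[3] = szz - ph;
  o.ok = true;
  return true;
}

// Element residual: 12 entries.  Returns false on an inverted configuration.
static bool elem_residual(const double Xe[4][2], const double de[12],
                          const double de_old[12], double dt,
                          const double *cfcd0, const double *nfl0,
                          const double *fib, int ndir, const Pars &pars,
                          int axisym, double swell, double res[12]) {
  GpOut o[4];
  for (int q = 0; q < 12; q++) res[q] = 0.0;
  double wsum = 0.0, pbar = 0.0, pbar_old = 0.0, Nbar[4] = {0, 0, 0, 0};

  for (int g = 0; g < 4; g++) {
    if (!gp_eval(g, Xe, de, de_old, cfcd0[g], nfl0[g], fib + 4 * ndir * g,
                 ndir, pars, axisym, swell, o[g]))
      return false;
    const GpOut &q = o[g];
    double J2 = q.F2[0][0] * q.F2[1][1] - q.F2[0][1] * q.F2[1][0];
    // first Piola-Kirchhoff, in-plane block: P = J sig invF^T
    double iF[2][2] = {{ q.F2[1][1] / J2, -q.F2[0][1] / J2},
                       {-q.F2[1][0] / J2,  q.F2[0][0] / J2}};
    double sg[2][2] = {{q.sig[0], q.sig[2]}, {q.sig[2], q.sig[1]}};
    double P[2][2];
    for (int i = 0; i < 2; i++)
      for (int jj = 0; jj < 2; jj++)
        P[i][jj] = q.J * (sg[i][0] * iF[jj][0] + sg[i][1] * iF[jj][1]);
    double Pzz = q.J * q.sig[3] / q.lz;

    // material flux Q = -k J C^-1 gradX p  (C^-1 = invF invF^T, in-plane)
    double gpx = iF[0][0] * q.gradp[0] + iF[1][0] * q.gradp[1];  // spatial
    double gpy = iF[0][1] * q.gradp[0] + iF[1][1] * q.gradp[1];
    double Qx = -pars.k * q.J * (iF[0][0] * gpx + iF[0][1] * gpy);
    double Qy = -pars.k * q.J * (iF[1][0] * gpx + iF[1][1] * gpy);

    double Jdot = (q.J - q.Jold) / dt;
    for (int a = 0; a < 4; a++) {
      res[3 * a] += q.w * (q.dNdX[a][0] * P[0][0] + q.dNdX[a][1] * P[0][1]);
      res[3 * a + 1] += q.w * (q.dNdX[a][0] * P[1][0] + q.dNdX[a][1] * P[1][1]);
      if (axisym)
        res[3 * a] += q.w * q.N[a] * Pzz / q.r0;
      res[3 * a + 2] += q.w * (q.N[a] * Jdot -
                               (q.dNdX[a][0] * Qx + q.dNdX[a][1] * Qy));
    }
    wsum += q.w;
    pbar += q.w * q.pgp;
    pbar_old += q.w * q.pgp_old;
    for (int a = 0; a < 4; a++) Nbar[a] += q.w * q.N[a];
  }

  // pressure-projection stabilization of the equal-order pair (applied to
  // the rate of the fluctuating pressure), scaled by 1/G of the matrix
  if (pars.alpha > 0.0) {
    pbar /= wsum; pbar_old /= wsum;
    for (int a = 0; a < 4; a++) Nbar[a] /= wsum;
    double cstab = pars.alpha / pars.Gnf;
    for (int g = 0; g < 4; g++) {
      const GpOut &q = o[g];
      double dp = (q.pgp - pbar) - (q.pgp_old - pbar_old);
      for (int a = 0; a < 4; a++)
        res[3 * a + 2] += cstab * q.w * (q.N[a] - Nbar[a]) * dp / dt;
    }
  }
  return true;
}

static Pars unpack(const NumericVector &p) {
  Pars s;
  s.Ef = p[0]; s.Knf = p[1]; s.Gnf = p[2]; s.k = p[3]; s.cext = p[4];
  s.RT = p[5]; s.phi_int = p[6]; s.phi_ext = p[7]; s.gam = p[8];
  s.a0 = p[9]; s.kappa = p[10]; s.alpha = p[11];
  return s;
}

// [[Rcpp::export(name = ".assemble_up")]]
List assemble_up(NumericMatrix nodes, IntegerMatrix elems, NumericVector d,
                 NumericVector d_old, double dt, NumericVector gp_cfcd0,
                 NumericVector gp_nfl0, NumericMatrix fib, int ndir,
                 NumericVector pars, int axisym, double swell,
                 bool want_K) {
  int ne = elems.nrow();
  int ndof = d.size();
  Pars ps = unpack(pars);
  NumericVector R(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_K) { ti.reserve(ne * 144); tj.reserve(ne * 144); tx.reserve(ne * 144); }

  for (int e = 0; e < ne; e++) {
    double Xe[4][2], de[12], deo[12];
    int gdof[12];
    for (int a = 0; a < 4; a++) {
      int n = elems(e, a) - 1;
      Xe[a][0] = nodes(n, 0); Xe[a][1] = nodes(n, 1);
      for (int c = 0; c < 3; c++) {
        gdof[3 * a + c] = 3 * n + c;
        de[3 * a + c] = d[3 * n + c];
        deo[3 * a + c] = d_old[3 * n + c];
      }
    }
    const double *cf = &gp_cfcd0[4 * e];
    const double *nf = &gp_nfl0[4 * e];
    // fib is (ngp_total*ndir) x 4 column-major; build a contiguous row copy
    if (ndir > 16) stop("at most 16 fibril directions per point supported");
    double fbuf[4 * 64];
    int nrowfib = fib.nrow();
    for (int i = 0; i < 4 * ndir; i++) {
      int row = 4 * ndir * e + i;
      fbuf[4 * i] = fib[row];
      fbuf[4 * i + 1] = fib[row + nrowfib];
      fbuf[4 * i + 2] = fib[row + 2 * nrowfib];
      fbuf[4 * i + 3] = fib[row + 3 * nrowfib];
    }

    double res[12];
    if (!elem_residual(Xe, de, deo, dt, cf, nf, fbuf, ndir, ps, axisym,
                       swell, res))
      stop("inverted element %d during assembly", e + 1);
    for (int q = 0; q < 12; q++) R[gdof[q]] += res[q];

    if (want_K) {
      double dpert[12], rp[12];
      for (int q = 0; q < 12; q++) dpert[q] = de[q];
      for (int j = 0; j < 12; j++) {
        double h = 1e-7 * std::max(1.0, std::fabs(de[j]));
        dpert[j] = de[j] + h;
        if (!elem_residual(Xe, dpert, deo, dt, cf, nf, fbuf, ndir, ps,
                           axisym, swell, rp)) {
          dpert[j] = de[j] - h;  // fall back to backward difference
          if (!elem_residual(Xe, dpert, deo, dt, cf, nf, fbuf, ndir, ps,
                             axisym, swell, rp))
            stop("tangent evaluation failed in element %d", e + 1);
          h = -h;
        }
        dpert[j] = de[j];
        for (int i = 0; i < 12; i++) {
          double kij = (rp[i] - res[i]) / h;
          if (kij != 0.0) {
            ti.push_back(gdof[i] + 1);
            tj.push_back(gdof[j] + 1);
            tx.push_back(kij);
          }
        }
      }
    }
  }
  if (want_K)
    return List::create(_["R"] = R, _["i"] = wrap(ti), _["j"] = wrap(tj),
                        _["x"] = wrap(tx));
  return List::create(_["R"] = R);
}

// Per-Gauss-point fields for postprocessing: Hencky principal strains,
// deviatoric / max shear strain, fluid flux and velocity, current FCD,
// swelling pressure and total Cauchy stress components.
// [[Rcpp::export(name = ".gp_fields")]]
NumericMatrix gp_fields(NumericMatrix nodes, IntegerMatrix elems,
                        NumericVector d, NumericVector d_old, double dt,
                        NumericVector gp_cfcd0, NumericVector gp_nfl0,
                        NumericMatrix fib, int ndir, NumericVector pars,
                        int axisym, double swell) {
  int ne = elems.nrow();
  Pars ps = unpack(pars);
  int ncol = 19;
  if (ndir > 16) stop("at most 16 fibril directions per point supported");
  NumericMatrix out(ne * 4, ncol);
  int nrowfib = fib.nrow();

  for (int e = 0; e < ne; e++) {
    double Xe[4][2], de[12], deo[12];
    for (int a = 0; a < 4; a++) {
      int n = elems(e, a) - 1;
      Xe[a][0] = nodes(n, 0); Xe[a][1] = nodes(n, 1);
      for (int c = 0; c < 3; c++) {
        de[3 * a + c] = d[3 * n + c];
        deo[3 * a + c] = d_old[3 * n + c];
      }
    }
    double fbuf[4 * 64];
    for (int i = 0; i < 4 * ndir; i++) {
      int row = 4 * ndir * e + i;
      fbuf[4 * i] = fib[row];
      fbuf[4 * i + 1] = fib[row + nrowfib];
      fbuf[4 * i + 2] = fib[row + 2 * nrowfib];
      fbuf[4 * i + 3] = fib[row + 3 * nrowfib];
    }
    for (int g = 0; g < 4; g++) {
      GpOut q;
      if (!gp_eval(g, Xe, de, deo, gp_cfcd0[4 * e + g], gp_nfl0[4 * e + g],
                   fbuf + 4 * ndir * g, ndir, ps, axisym, swell, q))
        stop("inverted element %d in field extraction", e + 1);
      int r = 4 * e + g;
      // reference gp coords
      double xg = 0.0, yg = 0.0;
      for (int a = 0; a < 4; a++) { xg += q.N[a] * Xe[a][0]; yg += q.N[a] * Xe[a][1]; }
      // in-plane left Cauchy-Green eigenvalues -> Hencky principal strains
      double B11 = q.F2[0][0] * q.F2[0][0] + q.F2[0][1] * q.F2[0][1];
      double B22 = q.F2[1][0] * q.F2[1][0] + q.F2[1][1] * q.F2[1][1];
      double B12 = q.F2[0][0] * q.F2[1][0] + q.F2[0][1] * q.F2[1][1];
      double tr = 0.5 * (B11 + B22);
      double dd = std::sqrt(0.25 * (B11 - B22) * (B11 - B22) + B12 * B12);
      double e1 = 0.5 * std::log(tr + dd);
      double e2 = 0.5 * std::log(tr - dd);
      double e3 = std::log(q.lz);
      double edev = std::sqrt((e1 - e2) * (e1 - e2) + (e1 - e3) * (e1 - e3) +
                              (e2 - e3) * (e2 - e3)) / 3.0;
      double emax = std::max(e1, std::max(e2, e3));
      double emin = std::min(e1, std::min(e2, e3));
      // spatial Darcy flux and fluid velocity
      double J2 = q.F2[0][0] * q.F2[1][1] - q.F2[0][1] * q.F2[1][0];
      double iF[2][2] = {{ q.F2[1][1] / J2, -q.F2[0][1] / J2},
                         {-q.F2[1][0] / J2,  q.F2[0][0] / J2}};
      double gpx = iF[0][0] * q.gradp[0] + iF[1][0] * q.gradp[1];
      double gpy = iF[0][1] * q.gradp[0] + iF[1][1] * q.gradp[1];
      double qx = -ps.k * gpx, qy = -ps.k * gpy;
      double ns0 = 1.0 - gp_nfl0[4 * e + g];
      double evr = (q.J - ns0) / ns0;          // current void ratio
      double vfac = (evr > 0.0) ? (evr + 1.0) / evr : 0.0;
      double vx = qx * vfac, vy = qy * vfac;

      out(r, 0) = xg; out(r, 1) = yg; out(r, 2) = q.J;
      out(r, 3) = q.c; out(r, 4) = q.dpi; out(r, 5) = q.pgp;
      out(r, 6) = e1; out(r, 7) = e2; out(r, 8) = e3;
      out(r, 9) = edev; out(r, 10) = emax - emin;
      out(r, 11) = qx; out(r, 12) = qy;
      out(r, 13) = vx; out(r, 14) = vy;
      out(r, 15) = q.sig[0]; out(r, 16) = q.sig[1];
      out(r, 17) = q.sig[2]; out(r, 18) = q.sig[3];
    }
  }
  colnames(out) = CharacterVector::create(
      "x", "y", "J", "c_fcd", "dpi", "p", "eps1", "eps2", "eps3", "eps_dev",
      "eps_shr", "qx", "qy", "vx", "vy", "sxx", "syy", "sxy", "szz");
  return out;
}
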
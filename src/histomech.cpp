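#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Constitutive point: compressible neo-Hookean / HGO with tension-only fibres
// under the kinematics F3 = blockdiag(F2, lambda3).
//
// Energy  Psi = C10*(Ib1 - 3) + (1/D1)*(J - 1)^2
//             + [HGO] k1/(2 k2) * (exp(k2 E^2) - 1)   if E > 0
//         E   = kappa*(Ib1 - 3) + (1 - 3 kappa)*(Ib4 - 1)
// with Ib1 = J^(-2/3) * tr(C3), Ib4 = J^(-2/3) * a0.C2.a0, J = det(F2)*l3.
//
// State vector ordering: x = (F11, F21, F12, F22, l3).
// Gradient g = dPsi/dx (first Piola components P11,P21,P12,P22 and P33),
// Hessian H = d2Psi/dx2.
// ---------------------------------------------------------------------------

struct MatPar {
  int type;      // 0 = neo-Hookean, 1 = HGO
  double C10, D1, k1, k2, kappa;
};

static inline MatPar matpar_from(const NumericVector& m) {
  MatPar p;
  p.type  = (int)m[0];
  p.C10   = m[1];
  p.D1    = m[2];
  p.k1    = m[3];
  p.k2    = m[4];
  p.kappa = m[5];
  return p;
}

// Evaluate energy, gradient and (optionally) Hessian at a state.
// Returns false if J <= 0.
static bool point_eval(const double F[4], double l3,
                       const MatPar& p, double a0x, double a0y,
                       bool need_hess,
                       double& energy, double g[5], double H[25]) {
  const double F11 = F[0], F21 = F[1], F12 = F[2], F22 = F[3];
  const double J2 = F11 * F22 - F12 * F21;
  const double J  = J2 * l3;
  if (!(J > 0.0) || !(l3 > 0.0)) return false;

  const double C11 = F11 * F11 + F21 * F21;
  const double C22 = F12 * F12 + F22 * F22;
  const double C12 = F11 * F12 + F21 * F22;
  const double I1  = C11 + C22 + l3 * l3;
  const double m1  = F11 * a0x + F12 * a0y;   // F2 a0
  const double m2  = F21 * a0x + F22 * a0y;
  const double I4  = m1 * m1 + m2 * m2;

  const double Jm  = std::pow(J, -2.0 / 3.0);
  const double Ib1 = Jm * I1;
  const double Ib4 = Jm * I4;

  // first derivatives of J, I1, I4 w.r.t. x
  double dJ[5]  = { l3 * F22, -l3 * F12, -l3 * F21, l3 * F11, J2 };
  double dI1[5] = { 2 * F11, 2 * F21, 2 * F12, 2 * F22, 2 * l3 };
  double dI4[5] = { 2 * m1 * a0x, 2 * m2 * a0x, 2 * m1 * a0y, 2 * m2 * a0y, 0.0 };

  const double cJm = -(2.0 / 3.0) * Jm / J;   // d(J^-2/3)/dJ
  double dJm[5], dIb1[5], dIb4[5];
  for (int i = 0; i < 5; ++i) {
    dJm[i]  = cJm * dJ[i];
    dIb1[i] = Jm * dI1[i] + I1 * dJm[i];
    dIb4[i] = Jm * dI4[i] + I4 * dJm[i];
  }

  // fibre term
  double E = 0.0, fib = 0.0, fibp = 0.0, fibpp = 0.0;
  bool active = false;
  if (p.type == 1) {
    E = p.kappa * (Ib1 - 3.0) + (1.0 - 3.0 * p.kappa) * (Ib4 - 1.0);
    if (E > 0.0) {
      active = true;
      const double ex = std::exp(p.k2 * E * E);
      fib   = p.k1 / (2.0 * p.k2) * (ex - 1.0);
      fibp  = p.k1 * E * ex;
      fibpp = p.k1 * (1.0 + 2.0 * p.k2 * E * E) * ex;
    }
  }

  const double Psi1 = p.C10 + (active ? fibp * p.kappa : 0.0);
  const double Psi4 = active ? fibp * (1.0 - 3.0 * p.kappa) : 0.0;
  const double Up   = (2.0 / p.D1) * (J - 1.0);

  energy = p.C10 * (Ib1 - 3.0) + (1.0 / p.D1) * (J - 1.0) * (J - 1.0) + fib;
  for (int i = 0; i < 5; ++i)
    g[i] = Psi1 * dIb1[i] + Psi4 * dIb4[i] + Up * dJ[i];

  if (!need_hess) return true;

  // second derivatives of J, I1, I4 (constant / sparse)
  double HJ[25] = {0}, HI4[25] = {0};
  // HJ within F block: d2J/dF11 dF22 = l3 ; d2J/dF12 dF21 = -l3
  HJ[0 * 5 + 3] = HJ[3 * 5 + 0] = l3;
  HJ[1 * 5 + 2] = HJ[2 * 5 + 1] = -l3;
  // cross F - l3: dJ2/dF
  HJ[0 * 5 + 4] = HJ[4 * 5 + 0] = F22;
  HJ[1 * 5 + 4] = HJ[4 * 5 + 1] = -F12;
  HJ[2 * 5 + 4] = HJ[4 * 5 + 2] = -F21;
  HJ[3 * 5 + 4] = HJ[4 * 5 + 3] = F11;
  // HI1 = 2 I (diagonal), built inline below.
  // HI4: dm1 lives in (F11,F12), dm2 in (F21,F22)
  HI4[0 * 5 + 0] = 2 * a0x * a0x;
  HI4[0 * 5 + 2] = HI4[2 * 5 + 0] = 2 * a0x * a0y;
  HI4[2 * 5 + 2] = 2 * a0y * a0y;
  HI4[1 * 5 + 1] = 2 * a0x * a0x;
  HI4[1 * 5 + 3] = HI4[3 * 5 + 1] = 2 * a0x * a0y;
  HI4[3 * 5 + 3] = 2 * a0y * a0y;

  const double c2Jm = (10.0 / 9.0) * Jm / (J * J); // d2(J^-2/3)/dJ2

  for (int i = 0; i < 5; ++i) {
    for (int j = 0; j < 5; ++j) {
      const double HJm = c2Jm * dJ[i] * dJ[j] + cJm * HJ[i * 5 + j];
      const double HI1ij = (i == j) ? 2.0 : 0.0;
      const double HIb1 = Jm * HI1ij + dJm[i] * dI1[j] + dI1[i] * dJm[j]
                          + I1 * HJm;
      const double HIb4 = Jm * HI4[i * 5 + j] + dJm[i] * dI4[j]
                          + dI4[i] * dJm[j] + I4 * HJm;
      double h = Psi1 * HIb1 + Psi4 * HIb4
               + (2.0 / p.D1) * dJ[i] * dJ[j] + Up * HJ[i * 5 + j];
      if (active) {
        const double dEi = p.kappa * dIb1[i] + (1.0 - 3.0 * p.kappa) * dIb4[i];
        const double dEj = p.kappa * dIb1[j] + (1.0 - 3.0 * p.kappa) * dIb4[j];
        h += fibpp * dEi * dEj;
      }
      H[i * 5 + j] = h;
    }
  }
  return true;
}

// Cauchy stress (3x3) from state + gradient (first Piola components).
static void cauchy_from(const double F[4], double l3, const double g[5],
                        double sig[9]) {
  const double J = (F[0] * F[3] - F[2] * F[1]) * l3;
  const double P11 = g[0], P21 = g[1], P12 = g[2], P22 = g[3], P33 = g[4];
  double s11 = (P11 * F[0] + P12 * F[2]) / J;
  double s12 = (P11 * F[1] + P12 * F[3]) / J;
  double s21 = (P21 * F[0] + P22 * F[2]) / J;
  double s22 = (P21 * F[1] + P22 * F[3]) / J;
  double s33 = P33 * l3 / J;
  // symmetrize (s12 == s21 analytically)
  double s = 0.5 * (s12 + s21);
  sig[0] = s11; sig[1] = s;   sig[2] = 0.0;
  sig[3] = s;   sig[4] = s22; sig[5] = 0.0;
  sig[6] = 0.0; sig[7] = 0.0; sig[8] = s33;
}

// [[Rcpp::export(name = ".cpp_point")]]
List cpp_point(NumericVector Fvec, double l3, NumericVector mat,
               NumericVector a0, bool need_hess = true) {
  MatPar p = matpar_from(mat);
  double F[4] = { Fvec[0], Fvec[1], Fvec[2], Fvec[3] };
  double energy, g[5], H[25];
  if (!point_eval(F, l3, p, a0[0], a0[1], need_hess, energy, g, H))
    stop("non-positive Jacobian: J = det(F) * lambda3 must be > 0");
  double sig[9];
  cauchy_from(F, l3, g, sig);
  NumericVector gv(5);
  for (int i = 0; i < 5; ++i) gv[i] = g[i];
  NumericMatrix sm(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) sm(i, j) = sig[i * 3 + j];
  List out = List::create(_["energy"] = energy, _["grad"] = gv,
                          _["sigma"] = sm);
  if (need_hess) {
    NumericMatrix Hm(5, 5);
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j) Hm(i, j) = H[i * 5 + j];
    out["hess"] = Hm;
  }
  return out;
}

// Solve sigma33(F2, l3) = 0 for l3 by safeguarded Newton on g5 = dPsi/dl3.
// Returns l3; sets ok = false when no root is bracketed in [lo, hi].
static double solve_l3(const double F[4], const MatPar& p,
                       double a0x, double a0y, double l3init, bool& ok,
                       int* iters = nullptr) {
  const double lo = 0.05, hi = 20.0;
  double l3 = l3init;
  if (!(l3 > lo) || !(l3 < hi)) l3 = 1.0;
  double energy, g[5], H[25];
  double a = NA_REAL, b = NA_REAL; // bracket with g(a) < 0 < g(b) (g increasing)
  ok = false;
  for (int it = 0; it < 100; ++it) {
    if (!point_eval(F, l3, p, a0x, a0y, true, energy, g, H)) { l3 = 1.0; continue; }
    double sig[9];
    cauchy_from(F, l3, g, sig);
    double snorm = 0.0;
    for (int k = 0; k < 9; ++k) snorm += sig[k] * sig[k];
    snorm = std::sqrt(snorm);
    if (std::fabs(sig[8]) < 1e-10 * std::max(1.0, snorm)) {
      ok = true;
      if (iters) *iters = it;
      return l3;
    }
    if (g[4] < 0.0) { if (!R_finite(a) || l3 > a) a = l3; }
    else            { if (!R_finite(b) || l3 < b) b = l3; }
    double step = -g[4] / H[24];
    double l3n = l3 + step;
    if (!R_finite(l3n) || l3n <= lo || l3n >= hi ||
        std::fabs(step) > 0.5 * l3) {
      if (R_finite(a) && R_finite(b)) l3n = 0.5 * (a + b);
      else if (g[4] < 0.0) l3n = std::min(hi - 1e-6, l3 * 1.5);
      else l3n = std::max(lo + 1e-6, l3 * 0.6);
    }
    l3 = l3n;
  }
  return l3;
}

// Condensed plane-stress response at a material point.
// [[Rcpp::export(name = ".cpp_plane_stress")]]
List cpp_plane_stress(NumericVector Fvec, NumericVector mat, NumericVector a0,
                      double l3init = 1.0) {
  MatPar p = matpar_from(mat);
  double F[4] = { Fvec[0], Fvec[1], Fvec[2], Fvec[3] };
  bool ok; int iters = 0;
  double l3 = solve_l3(F, p, a0[0], a0[1], l3init, ok, &iters);
  if (!ok)
    stop("plane-stress condensation failed: no lambda3 root in [0.05, 20] "
         "(det F2 = %g)", F[0] * F[3] - F[2] * F[1]);
  double energy, g[5], H[25];
  point_eval(F, l3, p, a0[0], a0[1], true, energy, g, H);
  double sig[9];
  cauchy_from(F, l3, g, sig);
  NumericVector P(4);
  for (int i = 0; i < 4; ++i) P[i] = g[i];
  NumericMatrix A(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      A(i, j) = H[i * 5 + j] - H[i * 5 + 4] * H[4 * 5 + j] / H[24];
  NumericMatrix sm(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) sm(i, j) = sig[i * 3 + j];
  return List::create(_["lambda3"] = l3, _["energy"] = energy,
                      _["P"] = P, _["tangent"] = A, _["sigma"] = sm,
                      _["iterations"] = iters);
}

// ---------------------------------------------------------------------------
// FE assembly on a structured grid of square bilinear quads (side h), plane
// stress, total Lagrangian. u is the full nodal displacement vector
// (2 dofs per node, node id = iy*(nx+1) + ix, x fastest).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_assemble")]]
List cpp_assemble(NumericVector u, int nx, int ny, double h,
                  IntegerVector elabel, NumericVector eangle,
                  NumericMatrix mats, NumericVector l3cache,
                  bool need_K = true) {
  const int nel = nx * ny;
  const int nnode = (nx + 1) * (ny + 1);
  if ((int)u.size() != 2 * nnode) stop("u has wrong length");
  if ((int)elabel.size() != nel) stop("elabel has wrong length");
  const double gp = 1.0 / std::sqrt(3.0);
  const double xi[4]  = { -gp,  gp,  gp, -gp };
  const double eta[4] = { -gp, -gp,  gp,  gp };
  // shape gradients dN/dX at each gauss point: [gp][node][dim]
  double dN[4][4][2];
  for (int q = 0; q < 4; ++q) {
    const double x = xi[q], e = eta[q], s = 1.0 / (2.0 * h); // (1/4)*(2/h)
    dN[q][0][0] = -(1 - e) * s; dN[q][0][1] = -(1 - x) * s;
    dN[q][1][0] =  (1 - e) * s; dN[q][1][1] = -(1 + x) * s;
    dN[q][2][0] =  (1 + e) * s; dN[q][2][1] =  (1 + x) * s;
    dN[q][3][0] = -(1 + e) * s; dN[q][3][1] =  (1 - x) * s;
  }
  const double w = (h / 2.0) * (h / 2.0); // gauss weight * detJ

  MatPar pars[3];
  for (int l = 0; l < 3; ++l) {
    NumericVector row = mats(l, _);
    pars[l] = matpar_from(row);
  }

  NumericVector resid(2 * nnode);
  NumericVector Kvals(need_K ? 64 * nel : 0);
  NumericVector l3out = clone(l3cache);
  double energy = 0.0, sumJ = 0.0;
  double sumPF[4] = {0, 0, 0, 0}; // P F^T in-plane: [11,12,21,22]
  bool bad = false;

  for (int el = 0; el < nel && !bad; ++el) {
    const int ex = el % nx, ey = el / nx;
    int nd[4];
    nd[0] = ey * (nx + 1) + ex;
    nd[1] = ey * (nx + 1) + ex + 1;
    nd[2] = (ey + 1) * (nx + 1) + ex + 1;
    nd[3] = (ey + 1) * (nx + 1) + ex;
    double ue[4][2];
    for (int a = 0; a < 4; ++a) {
      ue[a][0] = u[2 * nd[a]];
      ue[a][1] = u[2 * nd[a] + 1];
    }
    const MatPar& p = pars[elabel[el]];
    double a0x = 1.0, a0y = 0.0;
    if (p.type == 1) {
      const double th = eangle[el];
      a0x = std::cos(th); a0y = std::sin(th);
    }
    double Kel[64] = {0};
    double rel[8] = {0};
    for (int q = 0; q < 4; ++q) {
      double F[4] = { 1, 0, 0, 1 }; // F11,F21,F12,F22
      for (int a = 0; a < 4; ++a) {
        F[0] += ue[a][0] * dN[q][a][0];
        F[2] += ue[a][0] * dN[q][a][1];
        F[1] += ue[a][1] * dN[q][a][0];
        F[3] += ue[a][1] * dN[q][a][1];
      }
      if (F[0] * F[3] - F[2] * F[1] <= 0.0) { bad = true; break; }
      bool ok;
      double l3 = solve_l3(F, p, a0x, a0y, l3out[4 * el + q], ok);
      if (!ok) { bad = true; break; }
      l3out[4 * el + q] = l3;
      double en, g[5], H[25];
      point_eval(F, l3, p, a0x, a0y, need_K, en, g, H);
      energy += w * en;
      sumJ += w * (F[0] * F[3] - F[2] * F[1]) * l3;
      // in-plane P F^T
      sumPF[0] += w * (g[0] * F[0] + g[2] * F[2]);
      sumPF[1] += w * (g[0] * F[1] + g[2] * F[3]);
      sumPF[2] += w * (g[1] * F[0] + g[3] * F[2]);
      sumPF[3] += w * (g[1] * F[1] + g[3] * F[3]);
      // residual: r[2a+i] += w * P[c(i,J)] dN_a/dX_J, c = 2*J + i
      for (int a = 0; a < 4; ++a) {
        rel[2 * a]     += w * (g[0] * dN[q][a][0] + g[2] * dN[q][a][1]);
        rel[2 * a + 1] += w * (g[1] * dN[q][a][0] + g[3] * dN[q][a][1]);
      }
      if (need_K) {
        // condensed in-plane tangent A[c1][c2]
        double A[16];
        for (int i = 0; i < 4; ++i)
          for (int j = 0; j < 4; ++j)
            A[i * 4 + j] = H[i * 5 + j] - H[i * 5 + 4] * H[4 * 5 + j] / H[24];
        for (int a = 0; a < 4; ++a) {
          for (int b = 0; b < 4; ++b) {
            for (int i = 0; i < 2; ++i) {
              for (int k = 0; k < 2; ++k) {
                double kij = 0.0;
                for (int Jd = 0; Jd < 2; ++Jd)
                  for (int Ld = 0; Ld < 2; ++Ld)
                    kij += A[(2 * Jd + i) * 4 + (2 * Ld + k)] *
                           dN[q][a][Jd] * dN[q][b][Ld];
                Kel[(2 * a + i) * 8 + (2 * b + k)] += w * kij;
              }
            }
          }
        }
      }
    }
    if (bad) break;
    for (int a = 0; a < 4; ++a) {
      resid[2 * nd[a]]     += rel[2 * a];
      resid[2 * nd[a] + 1] += rel[2 * a + 1];
    }
    if (need_K)
      for (int k = 0; k < 64; ++k) Kvals[64 * el + k] = Kel[k];
  }

  NumericVector pf(4);
  for (int i = 0; i < 4; ++i) pf[i] = sumPF[i];
  return List::create(_["ok"] = !bad, _["resid"] = resid,
                      _["Kvals"] = need_K ? (SEXP)Kvals : R_NilValue,
                      _["energy"] = energy, _["sumPF"] = pf,
                      _["sumJ"] = sumJ, _["l3cache"] = l3out);
}

// ---------------------------------------------------------------------------
// Mean intercept length sampling: for each direction, lay parallel lines
// over the raster and return total foreground length and run count.
// mask(row, col): row = y index from the bottom, col = x index.
// ---------------------------------------------------------------------------

// Background gaps shorter than mergeGap (in px) do not split a run: grid
// sampling of oblique lines otherwise fragments single intercepts along
// staircase boundaries and biases MIL low near diagonal directions.
// [[Rcpp::export(name = ".cpp_mil")]]
NumericMatrix cpp_mil(LogicalMatrix mask, NumericVector angles,
                      double spacing, double step = 0.5,
                      double mergeGap = 1.25) {
  const int H = mask.nrow(), W = mask.ncol();
  const double cx = W / 2.0, cy = H / 2.0;
  const double D = std::sqrt((double)W * W + (double)H * H);
  const int na = angles.size();
  NumericMatrix out(na, 2); // columns: total length, run count
  for (int k = 0; k < na; ++k) {
    const double th = angles[k];
    const double ux = std::cos(th), uy = std::sin(th);
    const double nxv = -uy, nyv = ux;
    double total = 0.0;
    long runs = 0;
    for (double o = -D / 2.0; o <= D / 2.0; o += spacing) {
      bool infg = false;
      bool hadRun = false;
      double gap = 0.0;
      for (double t = -D / 2.0; t <= D / 2.0; t += step) {
        const double x = cx + o * nxv + t * ux;
        const double y = cy + o * nyv + t * uy;
        const int ix = (int)std::floor(x), iy = (int)std::floor(y);
        bool fg = false;
        if (ix >= 0 && ix < W && iy >= 0 && iy < H)
          fg = mask(iy, ix);
        if (fg) {
          total += step;
          if (!infg) {
            if (!hadRun || gap > mergeGap) ++runs;
            infg = true;
            hadRun = true;
          }
        } else {
          if (infg) { infg = false; gap = step; }
          else gap += step;
        }
      }
    }
    out(k, 0) = total;
    out(k, 1) = (double)runs;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher), squared
// distances, seeds where seed(mask) is TRUE (distance 0 there).
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericMatrix cpp_edt(LogicalMatrix seed) {
  const int H = seed.nrow(), W = seed.ncol();
  const double INF = 1e20;
  NumericMatrix d2(H, W);
  // columns pass
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = seed(i, j) ? 0.0 : INF;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d2(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) d2(i, j) = std::sqrt(d[j]);
  }
  return d2;
}

// ---------------------------------------------------------------------------
// 4-connected component count of a logical mask (flood fill).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_n_components")]]
int cpp_n_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> seen(H * W, 0);
  std::vector<int> stack;
  int ncomp = 0;
  for (int s = 0; s < H * W; ++s) {
    const int si = s % H, sj = s / H;
    if (!mask(si, sj) || seen[s]) continue;
    ++ncomp;
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int i = cur % H, j = cur / H;
      const int di[4] = { 1, -1, 0, 0 }, dj[4] = { 0, 0, 1, -1 };
      for (int k = 0; k < 4; ++k) {
        const int ni = i + di[k], nj = j + dj[k];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        const int id = nj * H + ni;
        if (mask(ni, nj) && !seen[id]) {
          seen[id] = 1;
          stack.push_back(id);
        }
      }
    }
  }
  return ncomp;
}
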
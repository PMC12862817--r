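// McMurchie-Davidson evaluation of Gaussian integrals over Cartesian
// contracted basis functions: overlap, kinetic, nuclear attraction,
// two-electron repulsion, angular momentum about an arbitrary origin, and
// first derivatives with respect to nuclear coordinates (including the
// bra-only "half-derivative" overlaps and the operator derivative of the
// nuclear attraction).  Supports s, p, d (Cartesian) and is generic in l.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

constexpr int LMAX = 5;     // max 1D angular momentum incl. derivative shifts
constexpr int TMAX = 2 * LMAX + 1;

struct AO {
  int l[3];
  double A[3];
  int atom;                  // 1-based atom index
  std::vector<double> expo;
  std::vector<double> coef;
};

std::vector<AO> make_aos(const List& basis) {
  IntegerMatrix lmat = basis["l"];
  NumericMatrix cen = basis["center"];
  IntegerVector atom = basis["atom"];
  List expo = basis["expo"], coef = basis["coef"];
  int n = lmat.nrow();
  std::vector<AO> aos(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) { aos[i].l[d] = lmat(i, d); aos[i].A[d] = cen(i, d); }
    aos[i].atom = atom[i];
    aos[i].expo = as<std::vector<double>>(expo[i]);
    aos[i].coef = as<std::vector<double>>(coef[i]);
  }
  return aos;
}

// Boys function F_m(x) for m = 0..mmax.
void boys(double x, int mmax, double* F) {
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 36.0) {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    double ex = (x < 700.0) ? std::exp(-x) : 0.0;
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
    return;
  }
  // series for F_mmax, then stable downward recursion
  double t = 1.0 / (2.0 * mmax + 1.0), s = t;
  for (int k = 1; k < 300; ++k) {
    t *= 2.0 * x / (2.0 * mmax + 2.0 * k + 1.0);
    s += t;
    if (t < 1e-17 * s) break;
  }
  double ex = std::exp(-x);
  F[mmax] = ex * s;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// Hermite expansion coefficients E[i][j][t] for a 1D primitive pair.
struct E1d {
  double E[LMAX + 1][LMAX + 1][TMAX + 1];
  void build(int imax, int jmax, double a, double b, double AB) {
    double p = a + b, mu = a * b / p;
    double PA = -b * AB / p, PB = a * AB / p;  // P - A, P - B with AB = A - B
    for (int i = 0; i <= imax; ++i)
      for (int j = 0; j <= jmax; ++j)
        for (int t = 0; t <= TMAX; ++t) E[i][j][t] = 0.0;
    E[0][0][0] = std::exp(-mu * AB * AB);
    for (int i = 0; i < imax; ++i)
      for (int t = 0; t <= i; ++t) {
        E[i + 1][0][t]     += PA * E[i][0][t] + (t + 1.0) * E[i][0][t + 1];
        E[i + 1][0][t + 1] += E[i][0][t] / (2.0 * p);
      }
    for (int j = 0; j < jmax; ++j)
      for (int i = 0; i <= imax; ++i)
        for (int t = 0; t <= i + j; ++t) {
          E[i][j + 1][t]     += PB * E[i][j][t] + (t + 1.0) * E[i][j][t + 1];
          E[i][j + 1][t + 1] += E[i][j][t] / (2.0 * p);
        }
  }
};

// Hermite Coulomb integrals R_{tuv} (n = 0 slice) for orders up to tm,um,vm.
struct RHermite {
  std::vector<double> R;  // [t][u][v]
  int Tm, Um, Vm;
  double& at(int t, int u, int v) { return R[(t * (Um + 1) + u) * (Vm + 1) + v]; }
  void build(double alpha, const double* PQ, int tm, int um, int vm) {
    Tm = tm; Um = um; Vm = vm;
    int nmax = tm + um + vm;
    double x = alpha * (PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2]);
    std::vector<double> F(nmax + 1);
    boys(x, nmax, F.data());
    // Rn[n][t][u][v], recursion downward in n
    auto idx = [&](int t, int u, int v) { return (t * (um + 1) + u) * (vm + 1) + v; };
    int sz = (tm + 1) * (um + 1) * (vm + 1);
    std::vector<double> cur(sz, 0.0), nxt(sz, 0.0);
    R.assign(sz, 0.0);
    // build R^n_{tuv} iteratively: start from highest n (only 000 needed)
    std::vector<std::vector<double>> Rn(nmax + 1, std::vector<double>(sz, 0.0));
    for (int n = nmax; n >= 0; --n) {
      Rn[n][idx(0, 0, 0)] = std::pow(-2.0 * alpha, n) * F[n];
      if (n < nmax) {
        for (int t = 0; t <= tm; ++t)
          for (int u = 0; u <= um; ++u)
            for (int v = 0; v <= vm; ++v) {
              if (t + u + v == 0 || t + u + v > nmax - n) continue;
              double val = 0.0;
              if (t > 0) {
                val = PQ[0] * Rn[n + 1][idx(t - 1, u, v)];
                if (t > 1) val += (t - 1) * Rn[n + 1][idx(t - 2, u, v)];
              } else if (u > 0) {
                val = PQ[1] * Rn[n + 1][idx(t, u - 1, v)];
                if (u > 1) val += (u - 1) * Rn[n + 1][idx(t, u - 2, v)];
              } else {
                val = PQ[2] * Rn[n + 1][idx(t, u, v - 1)];
                if (v > 1) val += (v - 1) * Rn[n + 1][idx(t, u, v - 2)];
              }
              Rn[n][idx(t, u, v)] = val;
            }
      }
    }
    R = Rn[0];
  }
};

// ---- primitive kernels -----------------------------------------------------

// overlap of two primitives (unit prefactors; coefficients applied outside)
double prim_overlap(const int* l1, const int* l2, double a, double b,
                    const double* A, const double* B) {
  double p = a + b, s = 1.0;
  for (int d = 0; d < 3; ++d) {
    E1d E;
    E.build(l1[d], l2[d], a, b, A[d] - B[d]);
    s *= E.E[l1[d]][l2[d]][0];
  }
  return s * std::pow(M_PI / p, 1.5);
}

// <g1 | (x_m - O_m) | g2>
double prim_moment(const int* l1, const int* l2, double a, double b,
                   const double* A, const double* B, int m, const double* O) {
  double p = a + b, s = 1.0;
  double P[3];
  for (int d = 0; d < 3; ++d) P[d] = (a * A[d] + b * B[d]) / p;
  for (int d = 0; d < 3; ++d) {
    E1d E;
    E.build(l1[d], l2[d], a, b, A[d] - B[d]);
    if (d == m)
      s *= E.E[l1[d]][l2[d]][1] + (P[d] - O[d]) * E.E[l1[d]][l2[d]][0];
    else
      s *= E.E[l1[d]][l2[d]][0];
  }
  return s * std::pow(M_PI / p, 1.5);
}

// <g1 | 1/|r - C| | g2>  (positive integral; -Z applied by caller)
double prim_nuclear(const int* l1, const int* l2, double a, double b,
                    const double* A, const double* B, const double* C) {
  double p = a + b;
  double P[3], PC[3];
  for (int d = 0; d < 3; ++d) {
    P[d] = (a * A[d] + b * B[d]) / p;
    PC[d] = P[d] - C[d];
  }
  E1d Ex, Ey, Ez;
  Ex.build(l1[0], l2[0], a, b, A[0] - B[0]);
  Ey.build(l1[1], l2[1], a, b, A[1] - B[1]);
  Ez.build(l1[2], l2[2], a, b, A[2] - B[2]);
  int tm = l1[0] + l2[0], um = l1[1] + l2[1], vm = l1[2] + l2[2];
  RHermite R;
  R.build(p, PC, tm, um, vm);
  double s = 0.0;
  for (int t = 0; t <= tm; ++t)
    for (int u = 0; u <= um; ++u)
      for (int v = 0; v <= vm; ++v)
        s += Ex.E[l1[0]][l2[0]][t] * Ey.E[l1[1]][l2[1]][u] *
             Ez.E[l1[2]][l2[2]][v] * R.at(t, u, v);
  return s * 2.0 * M_PI / p;
}

// ---- contracted engines ----------------------------------------------------

typedef double (*PrimFun)(const int*, const int*, double, double,
                          const double*, const double*, const void*);

// Generic contracted 1e integral over a primitive kernel closure.
template <typename F>
double contract(const AO& u, const AO& v, F f) {
  double s = 0.0;
  for (size_t i = 0; i < u.expo.size(); ++i)
    for (size_t j = 0; j < v.expo.size(); ++j)
      s += u.coef[i] * v.coef[j] * f(u.l, v.l, u.expo[i], v.expo[j], u.A, v.A);
  return s;
}

double c_overlap(const AO& u, const AO& v) {
  return contract(u, v, [](const int* l1, const int* l2, double a, double b,
                           const double* A, const double* B) {
    return prim_overlap(l1, l2, a, b, A, B);
  });
}

double c_moment(const AO& u, const AO& v, int m, const double* O) {
  return contract(u, v, [&](const int* l1, const int* l2, double a, double b,
                            const double* A, const double* B) {
    return prim_moment(l1, l2, a, b, A, B, m, O);
  });
}

double c_nuclear1(const AO& u, const AO& v, const double* C) {
  return contract(u, v, [&](const int* l1, const int* l2, double a, double b,
                            const double* A, const double* B) {
    return prim_nuclear(l1, l2, a, b, A, B, C);
  });
}

// kinetic energy via l-shifted overlaps on the ket
double c_kinetic(const AO& u, const AO& v) {
  double s = 0.0;
  for (size_t i = 0; i < u.expo.size(); ++i)
    for (size_t j = 0; j < v.expo.size(); ++j) {
      double a = u.expo[i], b = v.expo[j];
      double t = b * (2.0 * (v.l[0] + v.l[1] + v.l[2]) + 3.0) *
                 prim_overlap(u.l, v.l, a, b, u.A, v.A);
      for (int d = 0; d < 3; ++d) {
        int lp[3] = {v.l[0], v.l[1], v.l[2]}; lp[d] += 2;
        t -= 2.0 * b * b * prim_overlap(u.l, lp, a, b, u.A, v.A);
        if (v.l[d] >= 2) {
          int lm[3] = {v.l[0], v.l[1], v.l[2]}; lm[d] -= 2;
          t -= 0.5 * v.l[d] * (v.l[d] - 1.0) * prim_overlap(u.l, lm, a, b, u.A, v.A);
        }
      }
      s += u.coef[i] * v.coef[j] * t;
    }
  return s;
}

// "derivative view" of an AO with respect to one coordinate of its center:
// d/dA_d chi = sum_k c_k [ 2 a_k (l_d+1 view) - l_d (l_d-1 view) ]
void make_deriv_views(const AO& u, int d, std::vector<AO>& out) {
  out.clear();
  AO up = u;
  up.l[d] += 1;
  for (size_t k = 0; k < up.coef.size(); ++k) up.coef[k] *= 2.0 * up.expo[k];
  out.push_back(up);
  if (u.l[d] > 0) {
    AO dn = u;
    dn.l[d] -= 1;
    for (size_t k = 0; k < dn.coef.size(); ++k) dn.coef[k] *= -(double)u.l[d];
    out.push_back(dn);
  }
}

// <u | (x_m - O_m) d/dx_d | v>  : derivative wrt the electron coordinate on
// the ket equals minus the derivative wrt the ket center.
double c_moment_ketgrad(const AO& u, const AO& v, int m, const double* O, int d) {
  // make_deriv_views gives d/dB_d; acting on the electron coordinate,
  // d/dx_d = -(d/dB_d) for a function centered at B.
  std::vector<AO> views;
  make_deriv_views(v, d, views);
  double s = 0.0;
  for (const AO& w : views) s += c_moment(u, w, m, O);
  return -s;
}

// ---- exported builders -----------------------------------------------------

} // namespace

// [[Rcpp::export]]
List cpp_aoints(List basis, NumericVector Z, NumericMatrix nuc,
                NumericVector origin) {
  std::vector<AO> aos = make_aos(basis);
  int n = aos.size(), nnuc = Z.size();
  arma::mat S(n, n), T(n, n), V(n, n, arma::fill::zeros);
  arma::cube ell(n, n, 3, arma::fill::zeros);
  double O[3] = {origin[0], origin[1], origin[2]};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      S(i, j) = S(j, i) = c_overlap(aos[i], aos[j]);
      T(i, j) = T(j, i) = c_kinetic(aos[i], aos[j]);
      double v = 0.0;
      for (int c = 0; c < nnuc; ++c) {
        double C[3] = {nuc(c, 0), nuc(c, 1), nuc(c, 2)};
        v -= Z[c] * c_nuclear1(aos[i], aos[j], C);
      }
      V(i, j) = V(j, i) = v;
    }
  // angular momentum (r - O) x grad, real antisymmetric
  int perm[3][2] = {{1, 2}, {2, 0}, {0, 1}};  // (beta) -> (gamma, delta)
  for (int b = 0; b < 3; ++b) {
    int g = perm[b][0], d = perm[b][1];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        ell(i, j, b) = c_moment_ketgrad(aos[i], aos[j], g, O, d) -
                       c_moment_ketgrad(aos[i], aos[j], d, O, g);
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["ellx"] = ell.slice(0), _["elly"] = ell.slice(1),
                      _["ellz"] = ell.slice(2));
}

// [[Rcpp::export]]
arma::mat cpp_cross_overlap(List basis1, List basis2) {
  std::vector<AO> a1 = make_aos(basis1), a2 = make_aos(basis2);
  arma::mat S(a1.size(), a2.size());
  for (size_t i = 0; i < a1.size(); ++i)
    for (size_t j = 0; j < a2.size(); ++j)
      S(i, j) = c_overlap(a1[i], a2[j]);
  return S;
}

namespace {

double prim_eri(const int* l1, double a, const double* A,
                const int* l2, double b, const double* B,
                const int* l3, double c, const double* C,
                const int* l4, double d, const double* D) {
  double p = a + b, q = c + d;
  double P[3], Q[3], PQ[3];
  for (int k = 0; k < 3; ++k) {
    P[k] = (a * A[k] + b * B[k]) / p;
    Q[k] = (c * C[k] + d * D[k]) / q;
    PQ[k] = P[k] - Q[k];
  }
  double alpha = p * q / (p + q);
  E1d E1[3], E2[3];
  for (int k = 0; k < 3; ++k) {
    E1[k].build(l1[k], l2[k], a, b, A[k] - B[k]);
    E2[k].build(l3[k], l4[k], c, d, C[k] - D[k]);
  }
  int tm = l1[0] + l2[0] + l3[0] + l4[0];
  int um = l1[1] + l2[1] + l3[1] + l4[1];
  int vm = l1[2] + l2[2] + l3[2] + l4[2];
  RHermite R;
  R.build(alpha, PQ, tm, um, vm);
  double s = 0.0;
  for (int t = 0; t <= l1[0] + l2[0]; ++t)
    for (int u = 0; u <= l1[1] + l2[1]; ++u)
      for (int v = 0; v <= l1[2] + l2[2]; ++v) {
        double e1 = E1[0].E[l1[0]][l2[0]][t] * E1[1].E[l1[1]][l2[1]][u] *
                    E1[2].E[l1[2]][l2[2]][v];
        if (e1 == 0.0) continue;
        for (int tt = 0; tt <= l3[0] + l4[0]; ++tt)
          for (int uu = 0; uu <= l3[1] + l4[1]; ++uu)
            for (int vv = 0; vv <= l3[2] + l4[2]; ++vv) {
              double e2 = E2[0].E[l3[0]][l4[0]][tt] * E2[1].E[l3[1]][l4[1]][uu] *
                          E2[2].E[l3[2]][l4[2]][vv];
              if (e2 == 0.0) continue;
              double sign = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
              s += e1 * e2 * sign * R.at(t + tt, u + uu, v + vv);
            }
      }
  return s * 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
}

double c_eri(const AO& u, const AO& v, const AO& w, const AO& x) {
  double s = 0.0;
  for (size_t i = 0; i < u.expo.size(); ++i)
    for (size_t j = 0; j < v.expo.size(); ++j)
      for (size_t k = 0; k < w.expo.size(); ++k)
        for (size_t l = 0; l < x.expo.size(); ++l)
          s += u.coef[i] * v.coef[j] * w.coef[k] * x.coef[l] *
               prim_eri(u.l, u.expo[i], u.A, v.l, v.expo[j], v.A,
                        w.l, w.expo[k], w.A, x.l, x.expo[l], x.A);
  return s;
}

} // namespace

// chemists' notation (ij|kl), full 8-fold symmetry
// [[Rcpp::export]]
NumericVector cpp_eri(List basis) {
  std::vector<AO> aos = make_aos(basis);
  int n = aos.size();
  NumericVector out((R_xlen_t)n * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  auto I = [&](int i, int j, int k, int l) -> R_xlen_t {
    return ((R_xlen_t)((l * n + k) * n + j)) * n + i;
  };
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j)
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= (k == i ? j : k); ++l) {
          double v = c_eri(aos[i], aos[j], aos[k], aos[l]);
          out[I(i, j, k, l)] = out[I(j, i, k, l)] = out[I(i, j, l, k)] =
            out[I(j, i, l, k)] = out[I(k, l, i, j)] = out[I(l, k, i, j)] =
            out[I(k, l, j, i)] = out[I(l, k, j, i)] = v;
        }
  return out;
}

// Derivatives of S, T, V with respect to coordinate `dim` (0-based) of atom
// `atom` (1-based).  Returns the bra-only half-derivative overlap and the
// full S^R, T^R, V^R (V^R includes the operator derivative).
// [[Rcpp::export]]
List cpp_deriv_1e(List basis, NumericVector Z, NumericMatrix nuc,
                  int atom, int dim) {
  std::vector<AO> aos = make_aos(basis);
  int n = aos.size(), nnuc = Z.size();
  arma::mat halfS(n, n, arma::fill::zeros), TR(n, n, arma::fill::zeros),
            VR(n, n, arma::fill::zeros);
  std::vector<AO> views;
  for (int i = 0; i < n; ++i) {
    if (aos[i].atom != atom) continue;
    make_deriv_views(aos[i], dim, views);
    for (const AO& du : views)
      for (int j = 0; j < n; ++j) {
        halfS(i, j) += c_overlap(du, aos[j]);
        TR(i, j) += c_kinetic(du, aos[j]);
        TR(j, i) += c_kinetic(aos[j], du);
        double v = 0.0;
        for (int c = 0; c < nnuc; ++c) {
          double C[3] = {nuc(c, 0), nuc(c, 1), nuc(c, 2)};
          v -= Z[c] * c_nuclear1(du, aos[j], C);
        }
        VR(i, j) += v;
        VR(j, i) += v;  // <j | 1/r | du> = <du | 1/r | j> (real)
      }
  }
  // operator derivative of the nuclear attraction for the displaced nucleus:
  // translational invariance: dV_C/dC = -(bra + ket derivatives of V_C)
  double C[3] = {nuc(atom - 1, 0), nuc(atom - 1, 1), nuc(atom - 1, 2)};
  double Zc = Z[atom - 1];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double v = 0.0;
      make_deriv_views(aos[i], dim, views);
      for (const AO& du : views) v += c_nuclear1(du, aos[j], C);
      make_deriv_views(aos[j], dim, views);
      for (const AO& dv : views) v += c_nuclear1(aos[i], dv, C);
      // dV/dC = -Z * d/dC <i|1/r_C|j> = -Z * ( - (bra' + ket') ) = +Z*(bra'+ket')
      VR(i, j) += Zc * v;
      if (i != j) VR(j, i) += Zc * v;
    }
  arma::mat SR = halfS + halfS.t();
  return List::create(_["halfS"] = halfS, _["S_R"] = SR, _["T_R"] = TR,
                      _["V_R"] = VR, _["h_R"] = arma::mat(TR + VR));
}

// Derivative of the chemists' ERI tensor with respect to coordinate `dim`
// of atom `atom`.
// [[Rcpp::export]]
NumericVector cpp_eri_deriv(List basis, int atom, int dim) {
  std::vector<AO> aos = make_aos(basis);
  int n = aos.size();
  NumericVector out((R_xlen_t)n * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  auto I = [&](int i, int j, int k, int l) -> R_xlen_t {
    return ((R_xlen_t)((l * n + k) * n + j)) * n + i;
  };
  std::vector<AO> views;
  // derivative acts on each of the four slots whose AO sits on `atom`;
  // use 4-fold symmetry in (ij) and (kl) pair swaps plus bra-ket swap.
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j)
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= (k == i ? j : k); ++l) {
          double v = 0.0;
          if (aos[i].atom == atom) {
            make_deriv_views(aos[i], dim, views);
            for (const AO& d : views) v += c_eri(d, aos[j], aos[k], aos[l]);
          }
          if (aos[j].atom == atom) {
            make_deriv_views(aos[j], dim, views);
            for (const AO& d : views) v += c_eri(aos[i], d, aos[k], aos[l]);
          }
          if (aos[k].atom == atom) {
            make_deriv_views(aos[k], dim, views);
            for (const AO& d : views) v += c_eri(aos[i], aos[j], d, aos[l]);
          }
          if (aos[l].atom == atom) {
            make_deriv_views(aos[l], dim, views);
            for (const AO& d : views) v += c_eri(aos[i], aos[j], aos[k], d);
          }
          out[I(i, j, k, l)] = out[I(j, i, k, l)] = out[I(i, j, l, k)] =
            out[I(j, i, l, k)] = out[I(k, l, i, j)] = out[I(l, k, i, j)] =
            out[I(k, l, j, i)] = out[I(l, k, j, i)] = v;
        }
  return out;
}

// electric dipole integrals <mu | (r - O)_d | nu>
// [[Rcpp::export]]
List cpp_dipole(List basis, NumericVector origin) {
  std::vector<AO> aos = make_aos(basis);
  int n = aos.size();
  double O[3] = {origin[0], origin[1], origin[2]};
  arma::cube M(n, n, 3);
  for (int d = 0; d < 3; ++d)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= i; ++j) {
        double v = c_moment(aos[i], aos[j], d, O);
        M(i, j, d) = M(j, i, d) = v;
      }
  return List::create(_["x"] = M.slice(0), _["y"] = M.slice(1),
                      _["z"] = M.slice(2));
}
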
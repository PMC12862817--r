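// Determinant-space machinery: dense Hamiltonian construction by the
// Slater-Condon rules (generic one- and two-electron operators, real or
// complex), diagonal elements for preconditioning, and nonorthogonal
// wavefunction overlaps via determinants of occupied-MO cross-overlap
// minors (generalized Slater rules), used by the full finite-difference
// oracle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// excitation analysis between two sorted occupation lists (0-based orbs)
// returns degree; fills holes/parts (orbitals unique to I / to J) and the
// alignment sign.
int excitation(const int* I, const int* J, int nel, int* holes, int* parts,
               double& sign) {
  int nh = 0, np = 0;
  int posI[4], posJ[4];
  {
    int i = 0, j = 0;
    while (i < nel || j < nel) {
      if (i < nel && (j == nel || I[i] < J[j])) {
        if (nh < 3) { holes[nh] = I[i]; posI[nh] = i; }
        ++nh; ++i;
      } else if (j < nel && (i == nel || J[j] < I[i])) {
        if (np < 3) { parts[np] = J[j]; posJ[np] = j; }
        ++np; ++j;
      } else { ++i; ++j; }
    }
  }
  if (nh > 2) { sign = 0.0; return nh; }
  // sign = (-1)^{sum positions}
  int s = 0;
  for (int k = 0; k < nh; ++k) s += posI[k] + posJ[k];
  sign = (s % 2) ? -1.0 : 1.0;
  return nh;
}

template <typename T>
T get_g(const T* g, int n, int p, int q, int r, int s) {
  // column-major rank-4 array g[p, q, r, s]
  return g[((static_cast<R_xlen_t>(s) * n + r) * n + q) * n + p];
}

// matrix element <I|H|J> for H = sum h_pq a_p+ a_q + 1/4 sum <pq||rs> ...
template <typename T>
T sc_element(const int* I, const int* J, int nel, const T* h, const T* g,
             int n) {
  int holes[3], parts[3];
  double sign;
  int deg = excitation(I, J, nel, holes, parts, sign);
  if (deg > 2) return T(0);
  if (deg == 0) {
    T e = T(0);
    for (int i = 0; i < nel; ++i) {
      e += h[static_cast<R_xlen_t>(I[i]) * n + I[i]];
      for (int j = 0; j < nel; ++j)
        e += 0.5 * get_g(g, n, I[i], I[j], I[i], I[j]);
    }
    return e;
  }
  if (deg == 1) {
    int p = holes[0], q = parts[0];
    T e = h[static_cast<R_xlen_t>(q) * n + p];
    for (int i = 0; i < nel; ++i) {
      if (I[i] == p) continue;
      e += get_g(g, n, p, I[i], q, I[i]);
    }
    return sign * e;
  }
  // deg == 2
  return sign * get_g(g, n, holes[0], holes[1], parts[0], parts[1]);
}

} // namespace

// dets: ndet x nel integer matrix of sorted occupied spin orbitals (1-based)
// [[Rcpp::export]]
arma::mat cpp_hci_dense(IntegerMatrix dets, NumericMatrix h, NumericVector g) {
  int ndet = dets.nrow(), nel = dets.ncol(), n = h.nrow();
  std::vector<int> D(static_cast<size_t>(ndet) * nel);
  for (int i = 0; i < ndet; ++i)
    for (int e = 0; e < nel; ++e) D[static_cast<size_t>(i) * nel + e] = dets(i, e) - 1;
  arma::mat H(ndet, ndet);
  const double* hp = h.begin();
  const double* gp = g.begin();
  for (int i = 0; i < ndet; ++i)
    for (int j = 0; j <= i; ++j) {
      double v = sc_element(&D[static_cast<size_t>(i) * nel],
                            &D[static_cast<size_t>(j) * nel], nel, hp, gp, n);
      H(i, j) = v;
      if (i != j)
        H(j, i) = sc_element(&D[static_cast<size_t>(j) * nel],
                             &D[static_cast<size_t>(i) * nel], nel, hp, gp, n);
    }
  return H;
}

// [[Rcpp::export]]
arma::cx_mat cpp_hci_dense_cplx(IntegerMatrix dets, ComplexMatrix h,
                                ComplexVector g) {
  int ndet = dets.nrow(), nel = dets.ncol(), n = h.nrow();
  std::vector<int> D(static_cast<size_t>(ndet) * nel);
  for (int i = 0; i < ndet; ++i)
    for (int e = 0; e < nel; ++e) D[static_cast<size_t>(i) * nel + e] = dets(i, e) - 1;
  arma::cx_mat H(ndet, ndet);
  const std::complex<double>* hp =
      reinterpret_cast<const std::complex<double>*>(h.begin());
  const std::complex<double>* gp =
      reinterpret_cast<const std::complex<double>*>(g.begin());
  for (int i = 0; i < ndet; ++i)
    for (int j = 0; j < ndet; ++j)
      H(i, j) = sc_element(&D[static_cast<size_t>(i) * nel],
                           &D[static_cast<size_t>(j) * nel], nel, hp, gp, n);
  return H;
}

// diagonal of the dense Hamiltonian (for Davidson preconditioning)
// [[Rcpp::export]]
NumericVector cpp_hci_diag(IntegerMatrix dets, NumericMatrix h, NumericVector g) {
  int ndet = dets.nrow(), nel = dets.ncol(), n = h.nrow();
  NumericVector out(ndet);
  const double* hp = h.begin();
  const double* gp = g.begin();
  for (int i = 0; i < ndet; ++i) {
    double e = 0;
    for (int a = 0; a < nel; ++a) {
      int p = dets(i, a) - 1;
      e += hp[static_cast<R_xlen_t>(p) * n + p];
      for (int b = 0; b < nel; ++b) {
        int q = dets(i, b) - 1;
        e += 0.5 * get_g(gp, n, p, q, p, q);
      }
    }
    out[i] = e;
  }
  return out;
}

// <Psi_bra | Psi_ket> where the two CI expansions live in different
// (nonorthogonal) spin-orbital bases with cross-overlap matrix Smo
// (bra-orbital x ket-orbital).  The bra coefficients must already be
// conjugated by the caller.  Each determinant pair contributes
// c_I c_J det(Smo[occ_I, occ_J]).
// [[Rcpp::export]]
ComplexVector cpp_ci_overlap(IntegerMatrix detsL, ComplexVector cL,
                             IntegerMatrix detsR, ComplexVector cR,
                             ComplexMatrix Smo) {
  int nL = detsL.nrow(), nR = detsR.nrow(), nel = detsL.ncol();
  int n = Smo.nrow();
  arma::cx_mat S(reinterpret_cast<std::complex<double>*>(Smo.begin()),
                 n, Smo.ncol(), false);
  std::complex<double> acc(0.0, 0.0);
  const std::complex<double>* cl =
      reinterpret_cast<const std::complex<double>*>(cL.begin());
  const std::complex<double>* cr =
      reinterpret_cast<const std::complex<double>*>(cR.begin());
  arma::cx_mat M(nel, nel);
  for (int I = 0; I < nL; ++I) {
    if (std::abs(cl[I]) < 1e-300) continue;
    for (int J = 0; J < nR; ++J) {
      if (std::abs(cr[J]) < 1e-300) continue;
      for (int a = 0; a < nel; ++a)
        for (int b = 0; b < nel; ++b)
          M(a, b) = S(detsL(I, a) - 1, detsR(J, b) - 1);
      acc += cl[I] * cr[J] * arma::det(M);
    }
  }
  ComplexVector out(1);
  out[0].r = acc.real(); out[0].i = acc.imag();
  return out;
}

// Closed-shell Fock two-electron part J - K/2 with extended-precision
// accumulation: the finite-difference oracles divide orbital errors by the
// displacement step, so the plain double rounding floor of the contraction
// becomes the leading error of the whole scheme.
// [[Rcpp::export]]
arma::mat cpp_fock2e_ld(NumericVector eri, NumericMatrix D) {
  int n = D.nrow();
  const double* e = eri.begin();
  arma::mat F(n, n);
  auto idx = [&](int i, int j, int k, int l) -> R_xlen_t {
    return ((static_cast<R_xlen_t>(l) * n + k) * n + j) * n + i;
  };
  for (int mu = 0; mu < n; ++mu)
    for (int nu = 0; nu <= mu; ++nu) {
      long double acc = 0.0L;
      for (int la = 0; la < n; ++la)
        for (int si = 0; si < n; ++si) {
          long double d = D(la, si);
          acc += d * (static_cast<long double>(e[idx(mu, nu, la, si)]) -
                      0.5L * e[idx(mu, la, nu, si)]);
        }
      F(mu, nu) = F(nu, mu) = static_cast<double>(acc);
    }
  return F;
}

// complex variant (Hermitian density)
// [[Rcpp::export]]
arma::cx_mat cpp_fock2e_ld_cplx(NumericVector eri, ComplexMatrix D) {
  int n = D.nrow();
  const double* e = eri.begin();
  arma::cx_mat Dm(reinterpret_cast<std::complex<double>*>(D.begin()), n, n, true);
  arma::cx_mat F(n, n);
  auto idx = [&](int i, int j, int k, int l) -> R_xlen_t {
    return ((static_cast<R_xlen_t>(l) * n + k) * n + j) * n + i;
  };
  for (int mu = 0; mu < n; ++mu)
    for (int nu = 0; nu < n; ++nu) {
      long double ar = 0.0L, ai = 0.0L;
      for (int la = 0; la < n; ++la)
        for (int si = 0; si < n; ++si) {
          std::complex<double> d = Dm(la, si);
          long double w = static_cast<long double>(e[idx(mu, nu, la, si)]) -
                          0.5L * e[idx(mu, la, nu, si)];
          ar += d.real() * w;
          ai += d.imag() * w;
        }
      F(mu, nu) = std::complex<double>(static_cast<double>(ar),
                                       static_cast<double>(ai));
    }
  return F;
}

// C^T F C with extended-precision accumulation (see cpp_fock2e_ld)
// [[Rcpp::export]]
arma::mat cpp_mo_transform_ld(NumericMatrix F, NumericMatrix C) {
  int n = F.nrow(), m = C.ncol();
  std::vector<long double> tmp(static_cast<size_t>(n) * m);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < m; ++q) {
      long double acc = 0.0L;
      for (int j = 0; j < n; ++j)
        acc += static_cast<long double>(F(i, j)) * C(j, q);
      tmp[static_cast<size_t>(i) * m + q] = acc;
    }
  arma::mat out(m, m);
  for (int p = 0; p < m; ++p)
    for (int q = 0; q < m; ++q) {
      long double acc = 0.0L;
      for (int i = 0; i < n; ++i)
        acc += static_cast<long double>(C(i, p)) * tmp[static_cast<size_t>(i) * m + q];
      out(p, q) = static_cast<double>(acc);
    }
  return out;
}

// [[Rcpp::export]]
arma::cx_mat cpp_mo_transform_ld_cplx(ComplexMatrix F, ComplexMatrix C) {
  int n = F.nrow(), m = C.ncol();
  arma::cx_mat Fm(reinterpret_cast<std::complex<double>*>(F.begin()), n, n, true);
  arma::cx_mat Cm(reinterpret_cast<std::complex<double>*>(C.begin()), n, m, true);
  std::vector<std::complex<long double>> tmp(static_cast<size_t>(n) * m);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < m; ++q) {
      std::complex<long double> acc(0.0L, 0.0L);
      for (int j = 0; j < n; ++j)
        acc += std::complex<long double>(Fm(i, j)) *
               std::complex<long double>(Cm(j, q));
      tmp[static_cast<size_t>(i) * m + q] = acc;
    }
  arma::cx_mat out(m, m);
  for (int p = 0; p < m; ++p)
    for (int q = 0; q < m; ++q) {
      std::complex<long double> acc(0.0L, 0.0L);
      for (int i = 0; i < n; ++i)
        acc += std::conj(std::complex<long double>(Cm(i, p))) *
               tmp[static_cast<size_t>(i) * m + q];
      out(p, q) = std::complex<double>(static_cast<double>(acc.real()),
                                       static_cast<double>(acc.imag()));
    }
  return out;
}
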
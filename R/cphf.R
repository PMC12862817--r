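# Coupled-perturbed Hartree-Fock for nuclear-displacement (real) and
# magnetic-field (purely imaginary) perturbations, with the noncanonical
# perturbed-orbital convention: the redundant occupied-occupied and
# virtual-virtual orbital rotations are fixed as U = -S^chi/2 (zero for the
# field, whose basis functions carry no field dependence), so no
# orbital-energy denominators appear within those spaces.  With a frozen
# core, the core/active-occupied blocks are resolved canonically (the
# core-valence gap is large), because the frozen-core CI wavefunction does
# depend on how core orbitals mix into the valence space.

# J - K/2 response of the closed-shell Fock matrix to an AO density change
fock_response_mo <- function(ints, C, dD) {
  crossprod(C, fock_2e(ints$eri, dD) %*% C)
}

# exchange-only response to an antisymmetric (imaginary) AO density change:
# Delta F = -1/2 K(Dt)  (the Coulomb term vanishes by symmetry)
fock_response_imag_mo <- function(ints, C, Dt) {
  n <- nrow(Dt)
  K <- matrix(as.vector(matrix(aperm(array(ints$eri, c(n, n, n, n)),
                                     c(1, 3, 2, 4)), n * n, n * n) %*%
                          as.vector(Dt)), n, n)
  crossprod(C, (-0.5 * K) %*% C)
}

# AO density change from occupied-column rotations; only the vo block and
# the symmetric part of the oo block (fixed by orthonormality) contribute.
density_change <- function(C, n_occ, Uocc_cols) {
  # Uocc_cols: nbf(MO) x n_occ matrix of U_{p j} for occupied j
  dC <- C %*% Uocc_cols
  Cocc <- C[, seq_len(n_occ), drop = FALSE]
  2 * (dC %*% t(Cocc) + Cocc %*% t(dC))
}

#' Solve nuclear-displacement CPHF
#'
#' Solves the coupled-perturbed Hartree-Fock equations for the displacement
#' of one nuclear Cartesian coordinate.  The virtual-occupied block is
#' obtained from a dense linear solve; occupied-occupied and
#' virtual-virtual blocks follow the noncanonical convention
#' `U_pq = -S_pq^chi / 2` (with the core/active-occupied block replaced by
#' its canonical resolution when `n_frozen > 0`).
#'
#' @param scf an `scf_result`.
#' @param dints derivative integrals from [compute_derivative_integrals()].
#' @param n_frozen frozen-core spatial orbital count (affects only the
#'   occupied-occupied convention as described above).
#' @return Object of class `response_u`: `chi = "R"`, `U` (spin-orbital,
#'   real), `S_chi` (spin-orbital MO overlap derivative), plus the spatial
#'   `U_spatial`, `S_spatial`, and `halfS_mo` (spatial MO half-derivative
#'   overlap `<phi_p^R | phi_q>`).
#' @export
solve_cphf_nuclear <- function(scf, dints, n_frozen = 0) {
  C <- scf$C; eps <- scf$eps; ints <- scf$ints
  n <- ncol(C); nocc <- scf$n_occ; nvir <- n - nocc
  o <- seq_len(nocc); v <- nocc + seq_len(nvir)
  Sx <- crossprod(C, dints$S_R %*% C)
  Fx <- crossprod(C, (dints$h_R %*% C)) +
    fock_response_mo_deriv(ints, C, scf$D, dints)
  # fixed part of the density response: occupied-column rotations from the
  # symmetric oo part, U_oo = -Sx_oo/2
  U_fix <- matrix(0, n, nocc)
  U_fix[o, ] <- -Sx[o, o] / 2
  G_fix <- fock_response_mo(ints, C, density_change(C, nocc, U_fix))
  # unknowns x = U_ai (vo block)
  nun <- nvir * nocc
  A <- matrix(0, nun, nun)
  for (k in seq_len(nun)) {
    Uk <- matrix(0, n, nocc)
    ai <- arrayInd(k, c(nvir, nocc))
    Uk[v[ai[1]], ai[2]] <- 1
    Gk <- fock_response_mo(ints, C, density_change(C, nocc, Uk))
    A[, k] <- as.vector(Gk[v, o])
  }
  A <- A + diag(as.vector(outer(eps[v], eps[o], "-")), nrow = nun)
  b <- -as.vector(Fx[v, o] - Sx[v, o] %*% diag(eps[o], nocc) + G_fix[v, o])
  qr_A <- qr(A)
  if (any(abs(diag(qr.R(qr_A))) < 1e-10))
    stop("singular CPHF system: smallest pivot ",
         format(min(abs(diag(qr.R(qr_A))))))
  x <- solve(qr_A, b)
  Uvo <- matrix(x, nvir, nocc)
  U <- matrix(0, n, n)
  U[v, o] <- Uvo
  U[o, v] <- -Sx[o, v] - t(Uvo)
  U[o, o] <- -Sx[o, o] / 2
  U[v, v] <- -Sx[v, v] / 2
  if (n_frozen > 0) {
    # canonical resolution of the core/active-occupied rotations
    Ufull_occ <- U[, o, drop = FALSE]
    G_tot <- fock_response_mo(ints, C, density_change(C, nocc, Ufull_occ))
    F1 <- Fx + G_tot
    for (m in seq_len(n_frozen)) for (nn in seq(n_frozen + 1, nocc)) {
      U[m, nn] <- (F1[m, nn] - eps[nn] * Sx[m, nn]) / (eps[nn] - eps[m])
      U[nn, m] <- -Sx[nn, m] - U[m, nn]
    }
  }
  halfS_mo <- crossprod(C, dints$halfS %*% C)
  structure(list(chi = "R", reality = "real",
                 U = so_expand_1e(U), S_chi = so_expand_1e(Sx),
                 U_spatial = U, S_spatial = Sx,
                 halfS_mo = halfS_mo, halfS_so = so_expand_1e(halfS_mo),
                 lam_alpha = dints$lam_alpha, n_frozen = n_frozen),
            class = "response_u")
}

# derivative-integral Fock (fixed coefficients): h^R + D * (J - K/2)^R
fock_response_mo_deriv <- function(ints, C, D, dints) {
  n <- nrow(D)
  eriR <- array(dints$eri_R, c(n, n, n, n))
  J <- matrix(as.vector(matrix(eriR, n * n, n * n) %*% as.vector(D)), n, n)
  K <- matrix(as.vector(matrix(aperm(eriR, c(1, 3, 2, 4)), n * n, n * n) %*%
                          as.vector(D)), n, n)
  crossprod(C, (J - 0.5 * K) %*% C)
}

#' Solve magnetic-field CPHF
#'
#' The perturbation is the purely imaginary one-electron operator
#' `h^(H_beta) = (1/2) L_beta = -(i/2) ell_beta` (no GIAOs, so there is no
#' overlap-derivative source term and `U* + t(U) = 0`).  The response is
#' stored as the real matrix `u` with `U = i u`; anti-Hermiticity of U makes
#' `u` symmetric.  All-electron runs have exactly zero occupied-occupied and
#' virtual-virtual blocks; with a frozen core the core/active-occupied
#' rotations are retained (canonically resolved).
#'
#' @param scf an `scf_result`.
#' @param beta field axis, 1..3.
#' @param n_frozen frozen-core spatial orbital count.
#' @return `response_u` with `chi = "H"`, `u` (spin-orbital, real,
#'   symmetric), `u_spatial`, and `S_chi = 0`.
#' @export
solve_cphf_magnetic <- function(scf, beta, n_frozen = 0) {
  C <- scf$C; eps <- scf$eps; ints <- scf$ints
  n <- ncol(C); nocc <- scf$n_occ; nvir <- n - nocc
  o <- seq_len(nocc); v <- nocc + seq_len(nvir)
  mx <- crossprod(C, (-0.5 * ints$ell[[beta]]) %*% C)  # h^H = i * mx
  nun <- nvir * nocc
  A <- matrix(0, nun, nun)
  for (k in seq_len(nun)) {
    ai <- arrayInd(k, c(nvir, nocc))
    u_k <- matrix(0, n, n)
    u_k[v[ai[1]], ai[2]] <- 1; u_k[ai[2], v[ai[1]]] <- 1
    Dt <- imag_density_change(C, nocc, u_k)
    Gk <- fock_response_imag_mo(ints, C, Dt)
    A[, k] <- as.vector(Gk[v, o])
  }
  A <- A + diag(as.vector(outer(eps[v], eps[o], "-")), nrow = nun)
  x <- solve(A, -as.vector(mx[v, o]))
  u <- matrix(0, n, n)
  u[v, o] <- matrix(x, nvir, nocc)
  u[o, v] <- t(u[v, o])
  if (n_frozen > 0) {
    Dt <- imag_density_change(C, nocc, u)
    Gt <- fock_response_imag_mo(ints, C, Dt)
    M1 <- mx + Gt
    for (m in seq_len(n_frozen)) for (nn in seq(n_frozen + 1, nocc)) {
      u[m, nn] <- M1[m, nn] / (eps[nn] - eps[m])
      u[nn, m] <- u[m, nn]
    }
  }
  structure(list(chi = "H", reality = "imaginary", beta = beta,
                 u = so_expand_1e(u), u_spatial = u,
                 S_chi = matrix(0, 2 * n, 2 * n), n_frozen = n_frozen),
            class = "response_u")
}

# real antisymmetric Dt with Delta D = i * Dt, from occupied columns of u
imag_density_change <- function(C, n_occ, u) {
  Cocc <- C[, seq_len(n_occ), drop = FALSE]
  dC <- C %*% u[, seq_len(n_occ), drop = FALSE]
  2 * (dC %*% t(Cocc) - Cocc %*% t(dC))
}

#' @export
print.response_u <- function(x, ...) {
  cat(sprintf("<response_u> chi = %s (%s)\n", x$chi, x$reality))
  invisible(x)
}
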
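# Perturbed CI coefficients under intermediate normalization: derivative
# Hamiltonians (direct AO-derivative transforms plus CPHF U-coupling terms)
# and the projected linear response equations
#   (H - E) dc = -(dH - dE) c,   dc0 = 0,   dE = <c|dH|c> / <c|c>.
# For the magnetic perturbation everything is stored real with an implicit
# factor i; the response vector is then purely real as well.

# U-coupling of a one-electron MO matrix: d = hx + t(U) h + h U
couple_1e <- function(hx, h, U) hx + crossprod(U, h) + h %*% U

# imaginary-perturbation variant: U = i*u with u symmetric, so the bra-side
# coupling carries U+ = -i*u and the stored (factor-i) result is the
# commutator hx + h u - u h
couple_1e_imag <- function(hx, h, u) hx + h %*% u - u %*% h

# U-coupling of the antisymmetrized two-electron tensor:
# dg_pqrs = gx_pqrs + sum_t [U_tp g_tqrs + U_tq g_ptrs + U_tr g_pqts + U_ts g_pqrt]
couple_2e <- function(gx, g, U, slot_sign = c(1, 1, 1, 1)) {
  n <- dim(g)[1]
  out <- gx
  for (slot in 1:4) {
    perm <- seq_len(4); perm[1] <- slot; perm[slot] <- 1
    gp <- if (slot == 1) g else aperm(g, perm)
    x <- array(crossprod(U, matrix(gp, n, n^3)), dim(g))
    out <- out + slot_sign[slot] * (if (slot == 1) x else aperm(x, perm))
  }
  out
}

# imaginary variant: bra slots (1,2) couple through U+ = -i*u
couple_2e_imag <- function(g, u) couple_2e(array(0, dim(g)), g, u,
                                           slot_sign = c(-1, -1, 1, 1))

#' Assemble the derivative Hamiltonian in the spin-orbital MO basis
#'
#' For a nuclear perturbation (`resp$chi == "R"`) this is the MO transform
#' of the derivative AO integrals plus the CPHF U-coupling against the
#' unperturbed MO integrals; for a magnetic perturbation (`chi == "H"`) the
#' direct part is only the one-electron `-(1/2) ell_beta` term and the
#' result is the real matrix pair (dh, dg) with an implicit factor i.
#'
#' @param so spin-orbital store from [to_spin_orbital()].
#' @param scf the parent `scf_result`.
#' @param resp a `response_u` from [solve_cphf_nuclear()] or
#'   [solve_cphf_magnetic()].
#' @param dints derivative integrals (required when `resp$chi == "R"`).
#' @return List `dham` with `dh` (2n x 2n), `dg` (rank 4), `chi`.
#' @export
build_derivative_hamiltonian <- function(so, scf, resp, dints = NULL) {
  C <- scf$C
  if (resp$chi == "R") {
    if (is.null(dints)) stop("nuclear derivative Hamiltonian needs derivative integrals")
    hx <- so_expand_1e(crossprod(C, dints$h_R %*% C))
    gx <- so_antisymmetrize(ao2mo_eri(dints$eri_R, C))
    dh <- couple_1e(hx, so$h, resp$U)
    dg <- couple_2e(gx, so$g, resp$U)
    list(dh = dh, dg = dg, chi = "R", lam_alpha = resp$lam_alpha)
  } else if (resp$chi == "H") {
    mx <- so_expand_1e(crossprod(C, (-0.5 * scf$ints$ell[[resp$beta]]) %*% C))
    dh <- couple_1e_imag(mx, so$h, resp$u)
    dg <- couple_2e_imag(so$g, resp$u)
    list(dh = dh, dg = dg, chi = "H", beta = resp$beta)
  } else stop("mismatched perturbation tag: ", resp$chi)
}

# derivative Hamiltonian folded to the active space (reuses the frozen-core
# folding; works because folding is linear in (h, g))
dham_active <- function(dham, n_occ_so, n_frozen_so) {
  ci_hamiltonian(dham$dh, dham$dg, n_occ_so, n_frozen_so)
}

#' Solve the CI response equations
#'
#' Solves `(H - E) dc = -(dH - dE) c` in the excitation space with
#' `dc0 = 0` and `dE = <c|dH|c>/<c|c>` (zero for magnetic perturbations by
#' reality).  For MP2 the projected first-order amplitude equations are
#' differentiated instead (the LHS is diagonal in the canonical basis).
#'
#' @param ci a `ci_wavefunction` from [solve_ci()] or [mp2_coefficients()].
#' @param dham derivative Hamiltonian from [build_derivative_hamiltonian()].
#' @param tol residual threshold of the linear solve.
#' @return Object of class `ci_response`: `dc1`, `dc2`, `dE_elec`, `chi`,
#'   `reality`.
#' @export
solve_ci_response <- function(ci, dham, tol = 1e-11) {
  hamx <- dham_active(dham, ci$ham$n_occ_so, ci$ham$n_frozen_so)
  pk <- ci$pk
  if (ci$level == "MP2") return(mp2_response(ci, hamx, dham$chi))
  level <- ci$level
  Fx <- ci_fock(hamx); E0x <- ci_e0(hamx)
  sx <- sigma_cisd(hamx, Fx, E0x, ci$c0, ci$c1, ci$c2, level)
  svx <- pack_ci(pk, sx$s0, sx$s1, sx$s2)
  cvec <- pack_ci(pk, ci$c0, ci$c1, ci$c2)
  nrm2 <- sum(cvec^2)
  dE <- sum(cvec * svx) / nrm2
  if (dham$chi == "H") dE <- 0  # imaginary perturbation, real wavefunction
  rhs <- -(svx - dE * cvec)[-1]
  sig <- make_sigma(ci$ham, level, pk)
  E <- ci$E_elec
  matvec <- function(x) {
    v <- c(0, x)
    (sig(v) - E * v)[-1]
  }
  dgv <- ci_diag_approx(ci$ham, pk)[-1] - E
  x <- cg_solve(matvec, dgv, rhs, tol = tol)
  dcv <- unpack_ci(pk, c(0, x))
  resid <- matvec(x) - rhs
  structure(list(dc1 = dcv$c1, dc2 = dcv$c2, dE_elec = dE, chi = dham$chi,
                 reality = if (dham$chi == "H") "imaginary" else "real",
                 resid = max(abs(resid))),
            class = "ci_response")
}

#' @export
print.ci_response <- function(x, ...) {
  cat(sprintf("<ci_response> chi = %s, dE_elec = %.10g (residual %.2g)\n",
              x$chi, x$dE_elec, x$resid))
  invisible(x)
}

# derivative of the canonical first-order (MP2) amplitudes:
# (F - E_F) dc2 = -[(dF - dE_F) c]_D - d<ab||ij>
mp2_response <- function(ci, hamx, chi) {
  ham <- ci$ham
  no <- ham$no; nv <- ham$nv
  o <- seq_len(no); v <- no + seq_len(nv)
  f <- ci_fock(ham)
  eps <- Re(diag(f))
  den <- outer(outer(eps[o], eps[o], "+"), outer(eps[v], eps[v], "+"), "-")
  dF <- ci_fock(hamx)
  dEF <- sum(diag(dF)[o])
  # one-body action of dF on c2 (doubles block), minus the dEF c2 part:
  fham <- list(Ecore = 0, t = dF, g = array(0, dim(ham$g)), no = no, nv = nv)
  s <- sigma_cisd(fham, dF, dEF, 0, matrix(0, no, nv), ci$c2, "CID")
  # (F - E_F) dc2 = -den * dc2 on the doubles block, so
  # dc2 = [ (dF - dE_F)c + d<ab||ij> ] / den
  dc2 <- ((s$s2 - dEF * ci$c2) +
            aperm(hamx$g[v, v, o, o, drop = FALSE], c(3, 4, 1, 2))) / den
  structure(list(dc1 = matrix(0, no, nv), dc2 = dc2,
                 dE_elec = NA_real_, chi = chi,
                 reality = if (chi == "H") "imaginary" else "real",
                 resid = 0),
            class = "ci_response")
}
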
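# Complex restricted Hartree-Fock in a finite (imaginary) magnetic field.
# Used exclusively by the finite-difference oracles; all analytic code paths
# stay in real arithmetic.

#' Run RHF in a finite magnetic field
#'
#' Solves the complex Hermitian Fock equations with the perturbation
#' `h(B) = h0 + sum_beta B_beta * (1/2) L_beta`, where the matrix of
#' `L_beta` is `-i ell_beta`.  Orbitals are phase-aligned to a reference
#' coefficient matrix so finite-difference derivatives are well defined.
#'
#' @param ints an `integral_set`.
#' @param B numeric length-3 field vector (a.u.).
#' @param C_ref real reference MO coefficients used for the initial guess
#'   and for phase alignment.
#' @param conv convergence threshold (energy change and density RMS).
#' @param orb_conv threshold on the max |FDS - SDF| orbital gradient; the
#'   finite-difference oracles divide orbital errors by the field step, so
#'   orbitals must be converged far beyond the energy threshold.
#' @param maxiter iteration cap.
#' @param gauge orbital alignment against `C_ref`: `"group"` (Procrustes
#'   within near-degenerate groups, canonical otherwise) or `"block"`
#'   (maximum-overlap gauge over the occupied and virtual blocks).
#' @return List with complex `C`, real `eps`, `E_elec`, `E_scf`.
#' @export
run_rhf_field <- function(ints, B, C_ref, conv = 1e-13, orb_conv = 1e-13,
                          maxiter = 500, gauge = c("group", "block"),
                          n_frozen_gauge = 0) {
  gauge <- match.arg(gauge)
  n <- ints$nbf
  nocc <- n_electrons(ints$mol) / 2
  hB <- ints$h + 0i
  for (b in 1:3) if (B[b] != 0) hB <- hB - 0.5i * B[b] * ints$ell[[b]]
  S <- ints$S
  C <- C_ref + 0i
  E_old <- 0; errs <- list(); focks <- list()
  best_err <- Inf; stall <- 0
  for (it in seq_len(maxiter)) {
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- 2 * Cocc %*% Conj(t(Cocc))
    F <- hB + fock_2e_cplx(ints$eri, D)
    err <- F %*% D %*% S - S %*% D %*% F
    errs[[length(errs) + 1]] <- err; focks[[length(focks) + 1]] <- F
    if (length(errs) > 8) { errs <- errs[-1]; focks <- focks[-1] }
    if (length(errs) > 1) F <- diis_extrapolate_cplx(focks, errs)
    eg <- eigen_gen_herm(F, S)
    C <- eg$vectors; eps <- eg$values
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D_new <- 2 * Cocc %*% Conj(t(Cocc))
    # E = 1/2 Tr[D (h + F)] with F rebuilt from the new density
    E <- Re(0.5 * sum(D_new * t(hB + (hB + fock_2e_cplx(ints$eri, D_new)))))
    dE <- abs(E - E_old); drms <- sqrt(mean(Mod(D_new - D)^2))
    E_old <- E
    errn <- max(Mod(err))
    if (dE < conv && errn < orb_conv) break
    if (errn < best_err * 0.5) { best_err <- min(best_err, errn); stall <- 0 } else
      stall <- stall + 1
    best_err <- min(best_err, errn)
    if (dE < conv && stall >= 6) break
    if (it == maxiter) stop("field SCF failed to converge (dE = ", format(dE), ")")
  }
  # Newton polish (cf. run_rhf): real and imaginary parts of the gradient
  # respond through the real (J - K/2) and imaginary (-K/2) CPHF couplings
  o <- seq_len(nocc); vv <- setdiff(seq_len(n), o)
  A_re <- NULL; A_im <- NULL
  best_pol <- Inf; pol_stall <- 0
  for (sweep in 1:60) {
    Cocc <- C[, o, drop = FALSE]
    D <- 2 * Cocc %*% Conj(t(Cocc))
    F <- hB + fock_2e_cplx(ints$eri, D)
    Fmo <- cpp_mo_transform_ld_cplx(F, C)
    offd <- function(M) {
      if (nrow(M) < 2) return(0)
      M[cbind(seq_len(nrow(M)), seq_len(nrow(M)))] <- 0
      max(Mod(M))
    }
    errn <- max(Mod(Fmo[vv, o]), offd(Fmo[o, o, drop = FALSE]), offd(Fmo[vv, vv, drop = FALSE]))
    if (errn < max(orb_conv, 1e-16)) break
    if (errn < best_pol * 0.9) { best_pol <- errn; pol_stall <- 0 } else
      pol_stall <- pol_stall + 1
    if (pol_stall >= 5) break
    # canonicalize within the occupied and virtual blocks: the core/active
    # split must be exact or the frozen space at finite field is tilted
    if (length(o) > 1) {
      eo <- eigen((Fmo[o, o] + Conj(t(Fmo[o, o]))) / 2)
      C[, o] <- C[, o, drop = FALSE] %*% eo$vectors[, order(Re(eo$values))]
    }
    if (length(vv) > 1) {
      ev <- eigen((Fmo[vv, vv] + Conj(t(Fmo[vv, vv]))) / 2)
      C[, vv] <- C[, vv, drop = FALSE] %*% ev$vectors[, order(Re(ev$values))]
    }
    Fmo <- cpp_mo_transform_ld_cplx(F, C)
    if (is.null(A_re)) {
      Cr <- Re(C)  # couplings evaluated at the (nearly real) orbital frame
      nun <- length(vv) * nocc
      A_re <- matrix(0, nun, nun); A_im <- matrix(0, nun, nun)
      for (k in seq_len(nun)) {
        Uk <- matrix(0, n, nocc)
        ai <- arrayInd(k, c(length(vv), nocc))
        Uk[vv[ai[1]], ai[2]] <- 1
        dDr <- 2 * (Cr %*% Uk %*% t(Cr[, o, drop = FALSE]) +
                      Cr[, o, drop = FALSE] %*% t(Cr %*% Uk))
        Gk <- crossprod(Cr, Re(fock_2e_cplx(ints$eri, dDr + 0i)) %*% Cr)
        A_re[, k] <- as.vector(Gk[vv, o])
        dDi <- 2 * (Cr %*% Uk %*% t(Cr[, o, drop = FALSE]) -
                      Cr[, o, drop = FALSE] %*% t(Cr %*% Uk))
        Gi <- crossprod(Cr, Im(fock_2e_cplx(ints$eri, 1i * dDi)) %*% Cr)
        A_im[, k] <- as.vector(Gi[vv, o])
      }
      den <- diag(as.vector(outer(Re(diag(Fmo))[vv], Re(diag(Fmo))[o], "-")),
                  nrow = nun)
      A_re <- A_re + den; A_im <- A_im + den
    }
    xr <- solve(A_re, -as.vector(Re(Fmo[vv, o])))
    xi <- solve(A_im, -as.vector(Im(Fmo[vv, o])))
    X <- matrix(0 + 0i, n, n)
    X[vv, o] <- matrix(xr + 1i * xi, length(vv), nocc)
    X[o, vv] <- -Conj(t(X[vv, o]))
    C <- C %*% (diag(n) + X)
    for (rep in 1:2) {
      M <- cpp_mo_transform_ld_cplx(F * 0 + S + 0i, C)
      C <- C %*% ((3 * diag(n) - M) / 2)
    }
    eps <- Re(diag(cpp_mo_transform_ld_cplx(F, C)))
  }
  M <- Conj(t(C_ref)) %*% S %*% C
  al <- if (gauge == "block") align_max_overlap(C, M, nocc, n_frozen_gauge) else
    align_degenerate_groups(C, M, eps)
  C <- al$C
  C <- phase_align_to(C, C_ref, S)
  list(C = C, eps = eps, E_elec = E, E_scf = E + ints$enuc, nocc = nocc)
}

fock_2e_cplx <- function(eri, D) {
  cpp_fock2e_ld_cplx(eri, D)
}

diis_extrapolate_cplx <- function(focks, errs) {
  m <- length(errs)
  B <- matrix(0 + 0i, m + 1, m + 1)
  for (i in seq_len(m)) for (j in seq_len(m))
    B[i, j] <- sum(Conj(errs[[i]]) * errs[[j]])
  B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  w <- tryCatch(solve(B, rhs), error = function(e) c(rep(0, m - 1), 1, 0))
  F <- 0 * focks[[1]]
  for (i in seq_len(m)) F <- F + w[i] * focks[[i]]
  (F + Conj(t(F))) / 2
}

# generalized Hermitian eigenproblem F C = S C eps via symmetric
# orthogonalization (S real symmetric)
eigen_gen_herm <- function(F, S) {
  Sh <- sym_inv_sqrt(Re(S))
  Fp <- Sh %*% F %*% Sh
  Fp <- (Fp + Conj(t(Fp))) / 2
  e <- eigen(Fp, symmetric = TRUE)
  ord <- order(e$values)
  list(vectors = Sh %*% e$vectors[, ord], values = e$values[ord])
}

# multiply each MO by a unit phase so that its overlap with the reference
# orbital is real and positive
phase_align_to <- function(C, C_ref, S) {
  M <- Conj(t(C_ref)) %*% S %*% C
  for (p in seq_len(ncol(C))) {
    z <- M[p, p]
    if (Mod(z) < 1e-8)
      stop("phase alignment failed for orbital ", p,
           " (orbital reordering or degeneracy rotation at finite field)")
    C[, p] <- C[, p] * Conj(z) / Mod(z)
  }
  C
}
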
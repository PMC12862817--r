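# Restricted Hartree-Fock reference and the transformation to the
# spin-orbital basis used by all correlated equations.  Spin orbitals are
# interleaved: spin orbital 2p-1 is (spatial p, alpha), 2p is (p, beta), so
# the occupied spin orbitals of a closed-shell determinant are 1..N_elec.

#' Run restricted Hartree-Fock
#'
#' Core-Hamiltonian guess, DIIS acceleration, deterministic orbital phases
#' (the largest-magnitude coefficient of every MO is made positive).
#'
#' @param mol a [molecule()] (must be closed shell).
#' @param ints an `integral_set` from [compute_integrals()].
#' @param conv convergence threshold on the energy change and density RMS.
#' @param orb_conv threshold on the max |FDS - SDF| orbital gradient
#'   (iteration continues to this target or to stagnation; the
#'   finite-difference oracles need orbitals at the numerical floor).
#' @param maxiter maximum number of SCF iterations.
#' @return An object of class `scf_result`: `C` (AO x MO coefficients),
#'   `eps` (orbital energies), `E_scf` (total energy, a.u.), `n_occ`
#'   (occupied spatial MOs), `D` (AO density, `2 C_occ C_occ^T`), plus the
#'   inputs.
#' @export
run_rhf <- function(mol, ints, conv = 1e-10, orb_conv = 1e-11, maxiter = 200) {
  nel <- n_electrons(ints$mol)
  if (nel %% 2 != 0) stop("odd electron count: only closed-shell RHF is supported")
  nocc <- nel / 2
  S <- ints$S; h <- ints$h; n <- ints$nbf
  Shalf <- sym_inv_sqrt(S)
  # core guess
  C <- solve_roothaan(h, Shalf)$C
  D <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  E_old <- 0; errs <- list(); focks <- list()
  best_err <- Inf; stall <- 0
  for (it in seq_len(maxiter)) {
    F <- h + fock_2e(ints$eri, D)
    # DIIS
    err <- F %*% D %*% S - S %*% D %*% F
    errn <- max(abs(err))
    errs[[length(errs) + 1]] <- err; focks[[length(focks) + 1]] <- F
    if (length(errs) > 8) { errs <- errs[-1]; focks <- focks[-1] }
    if (length(errs) > 1) F <- diis_extrapolate(focks, errs)
    sol <- solve_roothaan(F, Shalf)
    C <- sol$C; eps <- sol$eps
    D_new <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    E <- 0.5 * sum(D_new * (h + (h + fock_2e(ints$eri, D_new))))
    dE <- abs(E - E_old); drms <- sqrt(mean((D_new - D)^2))
    D <- D_new; E_old <- E
    converged_E <- dE < conv
    if (converged_E && errn < orb_conv) break
    # stagnation at the numerical floor also terminates
    if (errn < best_err * 0.5) { best_err <- min(best_err, errn); stall <- 0 } else
      stall <- stall + 1
    best_err <- min(best_err, errn)
    if (converged_E && stall >= 6) break
    if (it == maxiter)
      stop("SCF failed to converge in ", maxiter,
           " iterations (dE = ", format(dE), ", |FDS-SDF| = ", format(errn), ")")
  }
  # Newton polish: the orbital gradient is driven to the numerical floor by
  # solving the exact orbital-rotation Jacobian (the CPHF coupling matrix).
  # DIIS alone stalls around 1e-12, which the finite-difference oracles
  # would amplify by 1/h.
  if (orb_conv < 1e-10) {
    o <- seq_len(nocc); vv <- setdiff(seq_len(n), o)
    A_jac <- NULL
    best_pol <- Inf; pol_stall <- 0
    for (sweep in 1:60) {
      F <- h + fock_2e(ints$eri, D)
      Fmo <- cpp_mo_transform_ld(F, C)
      # canonicality includes the occupied-occupied and virtual-virtual
      # blocks: the frozen-core canonical resolutions assume diag(F) exactly
      offd <- function(M) {
        if (nrow(M) < 2) return(0)
        M[cbind(seq_len(nrow(M)), seq_len(nrow(M)))] <- 0
        max(abs(M))
      }
      errn <- max(abs(Fmo[vv, o]), offd(Fmo[o, o, drop = FALSE]), offd(Fmo[vv, vv, drop = FALSE]))
      if (errn < max(orb_conv, 1e-16)) break
      if (errn < best_pol * 0.9) { best_pol <- errn; pol_stall <- 0 } else
        pol_stall <- pol_stall + 1
      if (pol_stall >= 5) break
      # rediagonalize within the occupied and virtual blocks
      if (length(o) > 1) {
        eo <- eigen((Fmo[o, o] + t(Fmo[o, o])) / 2, symmetric = TRUE)
        C[, o] <- C[, o, drop = FALSE] %*% eo$vectors[, order(eo$values)]
      }
      if (length(vv) > 1) {
        ev <- eigen((Fmo[vv, vv] + t(Fmo[vv, vv])) / 2, symmetric = TRUE)
        C[, vv] <- C[, vv, drop = FALSE] %*% ev$vectors[, order(ev$values)]
      }
      Fmo <- cpp_mo_transform_ld(F, C)
      if (is.null(A_jac)) {
        nun <- length(vv) * nocc
        A_jac <- matrix(0, nun, nun)
        for (k in seq_len(nun)) {
          Uk <- matrix(0, n, nocc)
          ai <- arrayInd(k, c(length(vv), nocc))
          Uk[vv[ai[1]], ai[2]] <- 1
          dD <- 2 * (C %*% Uk %*% t(C[, o, drop = FALSE]) +
                       C[, o, drop = FALSE] %*% t(C %*% Uk))
          Gk <- crossprod(C, fock_2e(ints$eri, dD) %*% C)
          A_jac[, k] <- as.vector(Gk[vv, o])
        }
        A_jac <- A_jac + diag(as.vector(outer(diag(Fmo)[vv], diag(Fmo)[o], "-")),
                              nrow = nun)
      }
      x <- solve(A_jac, -as.vector(Fmo[vv, o]))
      X <- matrix(0, n, n)
      X[vv, o] <- matrix(x, length(vv), nocc)
      X[o, vv] <- -t(X[vv, o])
      C <- C %*% (diag(n) + X)
      # extended-precision orthonormalization: a 1e-14 metric error couples
      # to the orbital-energy scale and would floor the gradient at ~1e-12
      for (rep in 1:2) {
        M <- cpp_mo_transform_ld(S, C)
        C <- C %*% ((3 * diag(n) - M) / 2)
      }
      D <- 2 * tcrossprod(C[, o, drop = FALSE])
    }
    eps <- diag(cpp_mo_transform_ld(h + fock_2e(ints$eri, D), C))
    E <- 0.5 * sum(D * (h + (h + fock_2e(ints$eri, D))))
  }
  C <- fix_phases(C)
  structure(list(C = C, eps = eps, E_scf = E + ints$enuc, E_elec = E,
                 n_occ = nocc, D = D, mol = ints$mol, ints = ints,
                 conv = conv),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result> E = %.12f a.u. (%d occupied MOs)\n", x$E_scf, x$n_occ))
  invisible(x)
}

sym_inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10) stop("overlap matrix is near-singular")
  e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
}

solve_roothaan <- function(F, Shalf) {
  Fp <- Shalf %*% F %*% Shalf
  e <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  list(C = Shalf %*% e$vectors[, ord], eps = e$values[ord])
}

# two-electron part of the closed-shell Fock matrix from an AO density
# (extended-precision accumulation in C++: the FD oracles divide orbital
# errors by a 1e-6 step, so the double-precision contraction floor matters)
fock_2e <- function(eri, D) {
  cpp_fock2e_ld(eri, D)
}

diis_extrapolate <- function(focks, errs) {
  m <- length(errs)
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) for (j in seq_len(m))
    B[i, j] <- sum(errs[[i]] * errs[[j]])
  B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  w <- tryCatch(solve(B, rhs), error = function(e) c(rep(0, m - 1), 1, 0))
  F <- 0 * focks[[1]]
  for (i in seq_len(m)) F <- F + w[i] * focks[[i]]
  F
}

fix_phases <- function(C) {
  for (p in seq_len(ncol(C))) {
    k <- which.max(abs(C[, p]))
    if (C[k, p] < 0) C[, p] <- -C[, p]
  }
  C
}

# ---- spin-orbital layer ----------------------------------------------------

# AO -> spatial MO transform of a chemists' ERI array (N^5 quarter transforms)
ao2mo_eri <- function(eri, C) {
  n <- nrow(C)
  x <- array(eri, c(n, n, n, n))
  for (k in 1:4) {
    x <- array(crossprod(C, matrix(x, n, n^3)), c(n, n, n, n))
    x <- aperm(x, c(2, 3, 4, 1))
  }
  x
}

# expand a spatial one-electron MO matrix to interleaved spin orbitals
so_expand_1e <- function(M) {
  n <- nrow(M)
  idx <- rep(seq_len(n), each = 2)
  spin <- rep(c(1, 2), n)
  M[idx, idx] * (outer(spin, spin, "=="))
}

# antisymmetrized spin-orbital integrals <pq||rs> from spatial chemists' MO ERI
so_antisymmetrize <- function(mo_eri) {
  n <- dim(mo_eri)[1]; n2 <- 2 * n
  idx <- rep(seq_len(n), each = 2)
  spin <- rep(c(1, 2), n)
  # <pq|rs> = (pr|qs) delta(sp,sr) delta(sq,ss)
  coul <- aperm(array(mo_eri[idx, idx, idx, idx], c(n2, n2, n2, n2)),
                c(1, 3, 2, 4))
  A <- coul * outer_delta(spin, n2, c(1, 3)) * outer_delta(spin, n2, c(2, 4))
  Ex <- aperm(A, c(1, 2, 4, 3))
  A - Ex
}

# delta(spin_i, spin_j) placed on dims d of a rank-4 array
outer_delta <- function(spin, n2, d) {
  m <- outer(spin, spin, "==") * 1
  perm <- integer(4); perm[d] <- 1:2; perm[setdiff(1:4, d)] <- 3:4
  aperm(array(m, c(n2, n2, n2, n2)), perm)
}

#' Transform to the spin-orbital basis
#'
#' Builds the antisymmetrized two-electron integrals `<pq||rs>` and the
#' one-electron core Hamiltonian in the interleaved spin-orbital MO basis.
#'
#' @param scf an `scf_result`.
#' @return Object of class `so_store`: `h` (2n x 2n), `g` (antisymmetrized
#'   `<pq||rs>`, rank-4), `nso`, `n_occ_so`, `C`, `eps_so`, `E_elec`,
#'   `enuc`.
#' @export
to_spin_orbital <- function(scf) {
  C <- scf$C
  mo_h <- crossprod(C, scf$ints$h %*% C)
  mo_eri <- ao2mo_eri(scf$ints$eri, C)
  g <- so_antisymmetrize(mo_eri)
  h <- so_expand_1e(mo_h)
  structure(list(h = h, g = g, nso = 2 * nrow(C), n_occ_so = 2 * scf$n_occ,
                 C = C, eps_so = rep(scf$eps, each = 2), E_elec = scf$E_elec,
                 enuc = scf$ints$enuc),
            class = "so_store")
}

#' @export
print.so_store <- function(x, ...) {
  cat(sprintf("<so_store> %d spin orbitals, %d occupied\n", x$nso, x$n_occ_so))
  invisible(x)
}

# Build a spin-orbital store from explicit MO coefficients over a given
# integral set (used by the finite-difference oracles, where the orbitals
# are not the canonical SCF solution of that geometry).  Complex capable.
so_build <- function(C, ints, n_occ) {
  cplx <- is.complex(C)
  Cc <- if (cplx) Conj(C) else C
  mo_h <- t(Cc) %*% ints$h %*% C
  mo_eri <- if (cplx) ao2mo_eri_cplx(ints$eri, C) else ao2mo_eri(ints$eri, C)
  g <- so_antisymmetrize(mo_eri)
  h <- so_expand_1e(mo_h)
  occ <- seq_len(2 * n_occ)
  E_elec <- Re(sum(diag(h)[occ]))
  for (i in occ) E_elec <- E_elec + Re(0.5 * sum(g[i, occ, i, occ][cbind(seq_along(occ), seq_along(occ))]))
  structure(list(h = h, g = g, nso = 2 * nrow(C), n_occ_so = 2 * n_occ,
                 C = C, eps_so = NULL, E_elec = E_elec, enuc = ints$enuc),
            class = "so_store")
}

# chemists' ERI transform with complex orbitals (bra slots conjugated)
ao2mo_eri_cplx <- function(eri, C) {
  n <- nrow(C)
  x <- array(eri + 0i, c(n, n, n, n))
  Cc <- Conj(C)
  for (k in 1:4) {
    Ck <- if (k %in% c(1, 3)) Cc else C
    x <- array(t(Ck) %*% matrix(x, n, n^3), c(n, n, n, n))
    x <- aperm(x, c(2, 3, 4, 1))
  }
  x
}
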
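# Two independent finite-difference AAT oracles.
#
# Mixed scheme: CI coefficient derivatives by central differences of
# phase-aligned re-solves (at displaced geometries / finite imaginary
# field), combined with the analytic determinant-derivative overlap
# structure; the orbital-rotation matrices are themselves extracted from
# the finite-difference MO overlaps, so the scheme is independent of the
# analytic CPHF solutions.
#
# Full-numerical scheme: the four-point difference of nonorthogonal
# wavefunction overlaps between displaced-geometry and complex
# field-perturbed CI expansions, evaluated with generalized Slater rules
# (determinants of occupied-MO cross-overlap minors).  Complex arithmetic
# is confined to this module.

# displaced-geometry SCF with orbitals sign-aligned (max overlap) to the
# reference.  Returns the integral set, aligned coefficients and the MO
# cross-overlap matrix M = C0^T S01 C.
fd_displaced_scf <- function(mol0, ints0, scf0, basis, lam_alpha, delta,
                             conv = 1e-13, gauge = c("group", "block"),
                             n_frozen_gauge = 0) {
  gauge <- match.arg(gauge)
  atom <- (lam_alpha - 1) %/% 3 + 1
  dim <- (lam_alpha - 1) %% 3 + 1
  m <- mol0
  m$coords[atom, dim] <- m$coords[atom, dim] + delta
  ints <- compute_integrals(m, basis, at_com = FALSE)
  scf <- run_rhf(m, ints, conv = conv, orb_conv = 1e-14)
  S01 <- cross_overlap(ints0$basis, ints$basis)
  M <- crossprod(scf0$C, S01 %*% scf$C)
  C <- scf$C
  # near-degenerate canonical orbitals rotate arbitrarily fast under the
  # displacement (and even well-separated ones contribute rotation noise
  # amplified by 1/gap); align to the reference by Procrustes rotations --
  # per degenerate group when the level of theory needs canonical orbitals
  # (HF/MP2), or over the whole occupied and virtual blocks for CI levels,
  # whose solver accepts any orthonormal gauge
  al <- if (gauge == "block") {
    align_max_overlap(C, M, scf0$n_occ, n_frozen_gauge)
  } else align_degenerate_groups(C, M, scf$eps)
  C <- al$C; M <- al$M
  for (p in seq_len(ncol(C))) {
    if (abs(M[p, p]) < 0.9)
      stop("orbital reordering detected at displaced geometry (orbital ", p,
           ", overlap ", format(M[p, p]), "); phase alignment impossible")
    if (Re(M[p, p]) < 0) { C[, p] <- -C[, p]; M[, p] <- -M[, p] }
  }
  list(ints = ints, C = C, M = M, scf = scf, eps = scf$eps)
}

# maximum-overlap gauge: Procrustes rotation of the core, active-occupied
# and virtual blocks onto the reference orbitals (real or complex C).  The
# core block is kept separate so that a frozen-core calculation still
# freezes the canonical core space (core/active rotations remain physical
# and are captured by the overlap derivative).
align_max_overlap <- function(C, M, nocc, nfz = 0) {
  blocks <- list(seq_len(nocc), setdiff(seq_len(ncol(C)), seq_len(nocc)))
  if (nfz > 0)
    blocks <- list(seq_len(nfz), setdiff(seq_len(nocc), seq_len(nfz)),
                   setdiff(seq_len(ncol(C)), seq_len(nocc)))
  for (blk in blocks) {
    sv <- svd(M[blk, blk, drop = FALSE])
    R <- sv$v %*% Conj(t(sv$u))
    C[, blk] <- C[, blk, drop = FALSE] %*% R
    M[, blk] <- M[, blk, drop = FALSE] %*% R
  }
  list(C = C, M = M)
}

# rotate orbitals within groups of (near-)equal orbital energy so that the
# reference overlap block M[grp, grp] becomes symmetric positive definite
# (orthogonal/unitary Procrustes); works for real and complex C.
align_degenerate_groups <- function(C, M, eps, tol = 2e-3) {
  n <- length(eps)
  grp_id <- cumsum(c(1, diff(eps) > tol))
  for (gid in unique(grp_id)) {
    g <- which(grp_id == gid)
    if (length(g) < 2) next
    sv <- svd(M[g, g, drop = FALSE])
    R <- sv$v %*% Conj(t(sv$u))
    C[, g] <- C[, g, drop = FALSE] %*% R
    M[, g] <- M[, g, drop = FALSE] %*% R
  }
  list(C = C, M = M)
}

# level-appropriate coefficient tensors from a spin-orbital store (real or
# complex); displaced/field solves are warm-started from the reference.
fd_solve_coefficients <- function(so, method, n_frozen, tol, guess_ci = NULL) {
  if (method == "HF") {
    hw <- hf_wavefunction(so, n_frozen)
    return(list(c1 = hw$c1, c2 = hw$c2))
  }
  if (method == "MP2") {
    mp <- mp2_so_amplitudes(so, n_frozen)
    return(mp)
  }
  level <- method
  ham <- ci_hamiltonian(so$h, so$g, so$n_occ_so, 2 * n_frozen)
  eshift <- Re(ci_e0(ham))
  ham$Ecore <- ham$Ecore - eshift
  pk <- ci_packing(ham$no, ham$nv, level)
  sig <- make_sigma(ham, level, pk)
  dg <- ci_diag_approx_generic(ham, pk)
  v0 <- if (!is.null(guess_ci)) {
    pack_ci(pk, 1, guess_ci$c1, guess_ci$c2)
  } else { v <- numeric(pk$len); v[1] <- 1; v }
  if (is.complex(so$h)) v0 <- v0 + 0i
  sol <- davidson(sig, dg, v0, tol = tol)
  rf <- refine_eigenpair(sig, dg, sol$vector, nsweep = 3, cg_tol = 1e-10)
  vec <- rf$vector / rf$vector[1]
  cv <- unpack_ci(pk, vec)
  list(c1 = cv$c1, c2 = cv$c2, E_elec = Re(rf$value) + eshift)
}

# integral set with the finite-field one-electron term folded into h
field_ints <- function(ints, B) {
  hB <- ints$h + 0i
  for (b in 1:3) if (B[b] != 0) hB <- hB - 0.5i * B[b] * ints$ell[[b]]
  ints$h <- hB
  ints
}

# complex-capable MP2 amplitudes (canonical orbitals assumed)
mp2_so_amplitudes <- function(so, n_frozen) {
  ham <- ci_hamiltonian(so$h, so$g, so$n_occ_so, 2 * n_frozen)
  no <- ham$no; nv <- ham$nv
  o <- seq_len(no); v <- no + seq_len(nv)
  eps <- Re(diag(ci_fock(ham)))
  den <- outer(outer(eps[o], eps[o], "+"), outer(eps[v], eps[v], "+"), "-")
  # the defining equation is -den * c2 = -<ab||ij>, i.e. the conjugate of
  # <ij||ab> when the orbitals are complex (finite magnetic field)
  gvvoo <- aperm(ham$g[v, v, o, o, drop = FALSE], c(3, 4, 1, 2))
  zero1 <- if (is.complex(so$h)) matrix(0 + 0i, no, nv) else matrix(0, no, nv)
  list(c1 = zero1, c2 = gvvoo / den)
}

# orbital-energy-difference diagonal usable for real and complex stores
ci_diag_approx_generic <- function(ham, pk) {
  ci_diag_approx(ham, pk)
}

#' Mixed finite-difference AAT oracle
#'
#' CI coefficient derivatives are computed by central differences
#' (re-solving the correlated wavefunction at displaced geometries and in a
#' finite imaginary magnetic field, phase-aligned to the reference), and
#' inserted into the determinant-derivative overlap structure of the
#' analytic formulation.  The orbital response matrices are likewise taken
#' from finite differences of the MO overlaps, so no analytic CPHF enters.
#'
#' @param mol a [molecule()].
#' @param basis basis-set name.
#' @param method `"HF"`, `"MP2"`, `"CID"`, `"CISD"`.
#' @param frozen_core freeze non-hydrogen cores.
#' @param h nuclear displacement step (bohr).
#' @param h_B magnetic field step (a.u.).
#' @param normalization `"full"` or `"intermediate"`.
#' @param conv SCF/CI convergence for the displaced solves.
#' @return An `aat_tensor`.
#' @export
mixed_fd_aat <- function(mol, basis, method = c("CISD", "CID", "MP2", "HF"),
                         frozen_core = TRUE, h = 1e-6, h_B = 1e-6,
                         normalization = c("full", "intermediate"),
                         conv = 1e-13, gauge = NULL) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  mol <- shift_to_com(mol)
  n_frozen <- if (frozen_core) sum(mol$charges > 2) else 0L
  ints <- compute_integrals(mol, basis)
  scf <- run_rhf(mol, ints, conv = conv, orb_conv = 1e-14)
  so <- to_spin_orbital(scf)
  ci <- switch(method,
    HF = hf_wavefunction(so, n_frozen),
    MP2 = mp2_coefficients(so, n_frozen),
    solve_ci(so, method, n_frozen, tol = 1e-13))
  guess <- list(c1 = ci$c1, c2 = ci$c2)
  if (is.null(gauge))
    gauge <- if (method %in% c("CID", "CISD")) "block" else "group"
  n_coord <- 3 * nrow(mol$coords)
  A_list <- vector("list", n_coord); dR_list <- vector("list", n_coord)
  for (la in seq_len(n_coord)) {
    dp <- fd_displaced_scf(mol, ints, scf, basis, la, +h, conv, gauge, n_frozen)
    dm <- fd_displaced_scf(mol, ints, scf, basis, la, -h, conv, gauge, n_frozen)
    A_list[[la]] <- so_expand_1e((dp$M - dm$M) / (2 * h))
    cp <- fd_solve_coefficients(so_build(dp$C, dp$ints, scf$n_occ), method,
                                n_frozen, 1e-13, guess)
    cm <- fd_solve_coefficients(so_build(dm$C, dm$ints, scf$n_occ), method,
                                n_frozen, 1e-13, guess)
    dR_list[[la]] <- list(dc1 = (cp$c1 - cm$c1) / (2 * h),
                          dc2 = (cp$c2 - cm$c2) / (2 * h))
  }
  v_list <- vector("list", 3); dH_list <- vector("list", 3)
  for (b in 1:3) {
    B <- c(0, 0, 0); B[b] <- h_B
    fp <- run_rhf_field(ints, B, scf$C, conv = conv, orb_conv = 1e-14,
                        gauge = gauge, n_frozen_gauge = n_frozen)
    Mb <- crossprod(scf$C, ints$S %*% fp$C)
    v_list[[b]] <- so_expand_1e(Im(Mb) / h_B)
    cb <- fd_solve_coefficients(so_build(fp$C, field_ints(ints, B), scf$n_occ),
                                method, n_frozen, 1e-13, guess)
    dH_list[[b]] <- list(dc1 = Im(cb$c1) / h_B, dc2 = Im(cb$c2) / h_B)
  }
  vals <- assemble_aat_core(ci, A_list, dR_list, v_list, dH_list)
  out <- new_aat(vals, normalization = "intermediate", method = method,
                 frozen_core = n_frozen, mol = mol)
  if (normalization == "full") {
    nd <- normalization_data(ci, dR_list)
    out <- apply_full_normalization(out, ci,
                                    lapply(v_list, function(u) list(u = u)),
                                    dH_list, nd)
    out$mol <- mol
  }
  out
}

# ---- full-numerical oracle -------------------------------------------------

#' Nonorthogonal CI wavefunction overlap
#'
#' `<Psi_bra | Psi_ket>` where the two CI expansions are built on different
#' (mutually nonorthogonal) MO bases.  Each determinant pair contributes
#' `conj(c_I) c_J det(Smo[occ_I, occ_J])` with `Smo` the spin-orbital MO
#' cross-overlap (generalized Slater rules).
#'
#' @param dets determinant table (rows of sorted occupied spin orbitals).
#' @param c_bra,c_ket coefficient vectors over `dets` (complex allowed; the
#'   bra is conjugated internally).
#' @param Smo_so spin-orbital MO cross-overlap matrix (bra x ket).
#' @return A complex scalar.
#' @export
ci_overlap <- function(dets, c_bra, c_ket, Smo_so) {
  nel <- ncol(dets)
  occ_min <- min(abs(diag(Smo_so[seq_len(nel), seq_len(nel), drop = FALSE])))
  if (occ_min < 1e-6)
    stop("singular occupied cross-overlap (pathological displacement)")
  z <- cpp_ci_overlap(dets, as.complex(Conj(c_bra)), dets,
                      as.complex(c_ket), as.matrix(Smo_so) + 0i)
  z[1]
}

#' Full finite-difference AAT oracle
#'
#' Four-point central difference of nonorthogonal wavefunction overlaps,
#' `I = [<Psi(R+h)|Psi(+ih_B)> - <Psi(R+h)|Psi(-ih_B)> - (+h -> -h)]
#' / (4 h h_B)`, using `Psi(-ih_B) = conj(Psi(+ih_B))`.  The naive
#' double-sum over determinant pairs restricts this oracle to the smallest
#' systems; it is the most independent check of the analytic tensors.
#'
#' @inheritParams mixed_fd_aat
#' @param h_R nuclear displacement step (bohr).
#' @return An `aat_tensor`.
#' @export
full_fd_aat <- function(mol, basis, method = c("CISD", "CID", "MP2", "HF"),
                        frozen_core = TRUE, h_R = 1e-6, h_B = 1e-6,
                        normalization = c("full", "intermediate"),
                        conv = 1e-13) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  mol <- shift_to_com(mol)
  n_frozen <- if (frozen_core) sum(mol$charges > 2) else 0L
  ints <- compute_integrals(mol, basis)
  scf <- run_rhf(mol, ints, conv = conv, orb_conv = 1e-14)
  so <- to_spin_orbital(scf)
  ci0 <- switch(method,
    HF = hf_wavefunction(so, n_frozen),
    MP2 = mp2_coefficients(so, n_frozen),
    solve_ci(so, method, n_frozen, tol = 1e-13))
  guess <- list(c1 = ci0$c1, c2 = ci0$c2)
  level <- if (method %in% c("HF", "MP2")) "CID" else method
  space <- det_space(so$n_occ_so, so$nso, 2 * n_frozen, level)
  to_vec <- function(cf, normz) {
    v <- tensor_to_detvec_cplx(space, 1, cf$c1, cf$c2)
    if (normz == "full") v <- v / sqrt(sum(Mod(v)^2))
    v
  }
  gauge <- if (method %in% c("CID", "CISD")) "block" else "group"
  # field-perturbed kets (reference geometry)
  kets <- lapply(1:3, function(b) {
    B <- c(0, 0, 0); B[b] <- h_B
    fp <- run_rhf_field(ints, B, scf$C, conv = conv, orb_conv = 1e-14,
                        gauge = gauge, n_frozen_gauge = n_frozen)
    cf <- fd_solve_coefficients(so_build(fp$C, field_ints(ints, B), scf$n_occ),
                                method, n_frozen, 1e-13, guess)
    list(C = fp$C, vec = to_vec(cf, normalization))
  })
  n_coord <- 3 * nrow(mol$coords)
  vals <- matrix(0, n_coord, 3)
  for (la in seq_len(n_coord)) {
    sides <- lapply(c(+1, -1), function(sgn) {
      d <- fd_displaced_scf(mol, ints, scf, basis, la, sgn * h_R, conv, gauge,
                            n_frozen)
      cf <- fd_solve_coefficients(so_build(d$C, d$ints, scf$n_occ), method,
                                  n_frozen, 1e-13, guess)
      list(C = d$C, basis = d$ints$basis, vec = to_vec(cf, normalization))
    })
    for (b in 1:3) {
      ims <- vapply(sides, function(sd) {
        S01 <- cross_overlap(sd$basis, ints$basis)
        Smo <- so_expand_1e(crossprod(sd$C, S01 %*% kets[[b]]$C))
        Im(ci_overlap(space$dets, sd$vec, kets[[b]]$vec, Smo))
      }, numeric(1))
      vals[la, b] <- (ims[1] - ims[2]) / (2 * h_R * h_B)
    }
  }
  new_aat(vals, normalization = normalization, method = method,
          frozen_core = n_frozen, mol = mol)
}

# complex-capable variant of tensor_to_detvec
tensor_to_detvec_cplx <- function(space, c0, c1, c2) {
  if (!is.complex(c1) && !is.complex(c2))
    return(tensor_to_detvec(space, c0, c1, c2))
  re <- tensor_to_detvec(space, Re(c0), Re(c1), Re(c2))
  im <- tensor_to_detvec(space, Im(c0), Im(c1), Im(c2))
  re + 1i * im
}
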
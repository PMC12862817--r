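# Backend-agnostic integral provider built on the package's own
# McMurchie-Davidson engine.  All magnetic integrals are referenced to the
# center-of-mass gauge origin; the basis carries no magnetic-field dependence
# (no GIAOs), so the field couples only through the purely imaginary angular
# momentum operator i * ell_beta.

#' Compute AO-basis integrals
#'
#' Computes the overlap, core Hamiltonian (kinetic + nuclear attraction),
#' chemists'-notation two-electron repulsion integrals and the real
#' antisymmetric angular-momentum matrices `ell` (such that the matrix of
#' the angular-momentum operator L_beta = -i (r - O) x grad is
#' `-i * ell_beta`) about the center-of-mass gauge origin.
#'
#' @param mol a [molecule()]; it is shifted to its center of mass internally
#'   if it is not already there (unless `at_com = FALSE`).
#' @param basis basis-set name (see [build_basis()]) or a prebuilt
#'   `basis_set` object.
#' @param at_com set to FALSE for displaced geometries in finite-difference
#'   work: the coordinates are then used as given and the gauge origin stays
#'   at (0,0,0), the center of mass of the undisplaced reference.
#' @return An object of class `integral_set`: list with `S`, `h`, `T`, `V`,
#'   `eri` (nbf^4 array, chemists' layout), `ell` (list of 3 antisymmetric
#'   matrices), `nbf`, `basis`, `mol`, `enuc`.
#' @export
compute_integrals <- function(mol, basis, at_com = TRUE) {
  if (at_com && !is_at_com(mol)) mol <- shift_to_com(mol)
  bs <- if (inherits(basis, "basis_set")) basis else build_basis(mol, basis)
  one <- cpp_aoints(bs, mol$charges, mol$coords, c(0, 0, 0))
  eri <- cpp_eri(bs)
  structure(list(S = one$S, T = one$T, V = one$V, h = one$T + one$V,
                 eri = eri,
                 ell = list(x = one$ellx, y = one$elly, z = one$ellz),
                 nbf = bs$nbf, basis = bs, mol = mol,
                 enuc = nuclear_repulsion(mol)),
            class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("<integral_set> %d basis functions (%s), E_nuc = %.10f\n",
              x$nbf, x$basis$name, x$enuc))
  invisible(x)
}

#' Compute nuclear-coordinate derivative integrals
#'
#' Derivatives of the AO integrals with respect to one nuclear Cartesian
#' coordinate, including the bra-only half-derivative overlap
#' `halfS[mu, nu] = <d(chi_mu)/dR | chi_nu>` that drives the
#' second-quantized core-derivative operators.  The full overlap derivative
#' satisfies `S_R = halfS + t(halfS)`.
#'
#' @param ints an `integral_set` from [compute_integrals()].
#' @param lam_alpha nuclear-coordinate index, 1-based over
#'   (atom1 x, atom1 y, atom1 z, atom2 x, ...).
#' @return List with `halfS`, `S_R`, `h_R`, `T_R`, `V_R`, `eri_R` and the
#'   `atom`/`dim` decoded from `lam_alpha`.
#' @export
compute_derivative_integrals <- function(ints, lam_alpha) {
  natom <- nrow(ints$mol$coords)
  if (lam_alpha < 1 || lam_alpha > 3 * natom)
    stop("lam_alpha out of range 1..", 3 * natom)
  atom <- (lam_alpha - 1) %/% 3 + 1
  dim <- (lam_alpha - 1) %% 3  # 0-based for C++
  one <- cpp_deriv_1e(ints$basis, ints$mol$charges, ints$mol$coords, atom, dim)
  eri_R <- cpp_eri_deriv(ints$basis, atom, dim)
  list(halfS = one$halfS, S_R = one$S_R, T_R = one$T_R, V_R = one$V_R,
       h_R = one$h_R, eri_R = eri_R, atom = atom, dim = dim + 1,
       lam_alpha = lam_alpha)
}

#' Cross-geometry AO overlap
#'
#' Overlap matrix between the basis functions of two (possibly different)
#' geometries, needed by the nonorthogonal wavefunction-overlap oracle.
#'
#' @param basis1,basis2 `basis_set` objects.
#' @return nbf1 x nbf2 overlap matrix.
#' @export
cross_overlap <- function(basis1, basis2) {
  cpp_cross_overlap(basis1, basis2)
}
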
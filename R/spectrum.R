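# VCD spectrum stage: nuclear AATs, per-mode rotatory strengths from a
# Hessian + atomic polar tensor, and Lorentzian-broadened spectra.
#
# Unit conventions: the electronic AAT is stored in the package's field
# convention (perturbation (1/2) B.L, no 1/c); the nuclear AAT below is the
# standard Stephens form J = Z/(4c) eps R.  rotatory_strengths() rescales
# the electronic part by 1/c so the two pair consistently, computes
# R_n = sum_beta [sum P S]_beta [sum M S]_beta  (atomic units, the harmonic
# frequency factors cancel between the electric and magnetic moments), and
# converts to 10^-44 esu^2 cm^2.

#' Nuclear contribution to the atomic axial tensor
#'
#' `J_{lam alpha, beta} = Z_lam/(4c) * eps_{alpha beta gamma} R_{lam gamma}`
#' (Stephens convention), antisymmetric in (alpha, beta) for each nucleus
#' and origin-dependent: the molecule must be at its center of mass.
#'
#' @param mol a [molecule()] at its center of mass.
#' @return An `aat_tensor` with method `"nuclear"`.
#' @export
nuclear_aat <- function(mol) {
  if (!is_at_com(mol))
    warning("geometry is not at the center of mass; the nuclear AAT is origin-dependent")
  c_au <- vcd_constants$fine_structure_c
  natom <- nrow(mol$coords)
  vals <- matrix(0, 3 * natom, 3)
  lev <- array(0, c(3, 3, 3))
  lev[1, 2, 3] <- lev[2, 3, 1] <- lev[3, 1, 2] <- 1
  lev[3, 2, 1] <- lev[2, 1, 3] <- lev[1, 3, 2] <- -1
  for (at in seq_len(natom)) for (al in 1:3) for (be in 1:3) {
    s <- 0
    for (ga in 1:3) s <- s + lev[al, be, ga] * mol$coords[at, ga]
    vals[(at - 1) * 3 + al, be] <- mol$charges[at] / (4 * c_au) * s
  }
  new_aat(vals, normalization = "full", method = "nuclear",
          frozen_core = 0L, mol = mol)
}

#' Read a whitespace-delimited Hessian or APT matrix
#'
#' @param path file of whitespace-separated numbers, one matrix row per
#'   line (comment lines starting with `#` are ignored).
#' @param nrow_expected,ncol_expected optional shape check; a mismatch is
#'   an error naming the expected dimensions.
#' @return Numeric matrix (a.u.).
#' @export
read_matrix_file <- function(path, nrow_expected = NULL, ncol_expected = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(unique(lengths(rows))) != 1)
    stop("ragged rows in matrix file ", path)
  m <- do.call(rbind, rows)
  if (!is.null(nrow_expected) && nrow(m) != nrow_expected)
    stop("matrix in ", path, " has ", nrow(m), " rows; expected ", nrow_expected)
  if (!is.null(ncol_expected) && ncol(m) != ncol_expected)
    stop("matrix in ", path, " has ", ncol(m), " columns; expected ", ncol_expected)
  m
}

#' Bundle vibrational data
#'
#' @param hessian 3N x 3N Cartesian Hessian (a.u.).
#' @param apt 3N x 3 atomic polar tensor (a.u.).
#' @param masses per-atom masses (amu).
#' @return A `vibrational_data` list.
#' @export
vibrational_data <- function(hessian, apt, masses) {
  n3 <- 3 * length(masses)
  if (!all(dim(hessian) == c(n3, n3)))
    stop("Hessian must be ", n3, " x ", n3)
  if (max(abs(hessian - t(hessian))) > 1e-8)
    stop("Hessian is not symmetric")
  if (!all(dim(apt) == c(n3, 3))) stop("APT must be ", n3, " x 3")
  structure(list(hessian = (hessian + t(hessian)) / 2, apt = apt,
                 masses = masses), class = "vibrational_data")
}

# orthogonal projector onto the complement of mass-weighted rigid
# translations and rotations
tr_projector <- function(mol) {
  amu <- vcd_constants$amu_to_me
  n <- nrow(mol$coords)
  sm <- sqrt(mol$masses * amu)
  vecs <- list()
  for (d in 1:3) {
    v <- matrix(0, n, 3); v[, d] <- sm
    vecs[[length(vecs) + 1]] <- as.vector(t(v))
  }
  lev <- list(c(2, 3), c(3, 1), c(1, 2))
  for (ax in 1:3) {
    v <- matrix(0, n, 3)
    a <- lev[[ax]][1]; b <- lev[[ax]][2]
    v[, a] <- sm * mol$coords[, b]
    v[, b] <- -sm * mol$coords[, a]
    vecs[[length(vecs) + 1]] <- as.vector(t(v))
  }
  B <- do.call(cbind, vecs)
  keep <- sqrt(colSums(B^2)) > 1e-10
  B <- B[, keep, drop = FALSE]
  Q <- qr.Q(qr(B))
  diag(3 * n) - tcrossprod(Q)
}

#' Per-mode rotatory strengths
#'
#' Diagonalizes the mass-weighted Hessian, removes the translational /
#' rotational zero modes (|freq| < `zero_cut` cm^-1), and contracts the APT
#' and total AAT (electronic + nuclear) with the normal modes:
#' `R_n = sum_beta [sum_{lam alpha} P S]_beta [sum_{lam alpha} M S]_beta`.
#' Reported in 10^-44 esu^2 cm^2.
#'
#' @param elec_aat electronic `aat_tensor` (must be fully normalized).
#' @param nuc_aat nuclear `aat_tensor` from [nuclear_aat()].
#' @param vib a [vibrational_data()].
#' @param zero_cut zero-mode threshold in cm^-1 (default 5).
#' @param project_tr project rigid translations/rotations out of the
#'   mass-weighted Hessian before diagonalizing (default TRUE; disable for
#'   synthetic single-mode test systems).
#' @return Object of class `spectrum_result`: `freqs` (cm^-1), `rotatory`
#'   (10^-44 esu^2 cm^2), `dipole_strength` contraction helpers, `modes`
#'   (mass-weighted eigenvectors).
#' @export
rotatory_strengths <- function(elec_aat, nuc_aat, vib, zero_cut = 5,
                               project_tr = TRUE) {
  if (elec_aat$normalization != "full")
    stop("electronic AAT must be fully normalized (got '",
         elec_aat$normalization, "')")
  n3 <- nrow(vib$hessian)
  if (nrow(elec_aat$values) != n3 || nrow(nuc_aat$values) != n3)
    stop("AAT/Hessian dimension mismatch: ", nrow(elec_aat$values), " vs ", n3)
  c_au <- vcd_constants$fine_structure_c
  amu <- vcd_constants$amu_to_me
  minv <- 1 / sqrt(rep(vib$masses, each = 3) * amu)
  Hmw <- vib$hessian * outer(minv, minv)
  # project out rigid translations and rotations (Eckart frame): at a
  # non-stationary geometry the rotational modes otherwise contaminate the
  # vibrational block
  if (project_tr && !is.null(elec_aat$mol)) {
    P <- tr_projector(elec_aat$mol)
    Hmw <- P %*% Hmw %*% P
  }
  ee <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  lam <- ee$values
  freqs_all <- sign(lam) * sqrt(abs(lam)) * vcd_constants$hartree_to_wavenumber
  keep <- abs(freqs_all) >= zero_cut
  ord <- order(freqs_all[keep], decreasing = TRUE)
  L <- ee$vectors[, keep, drop = FALSE][, ord, drop = FALSE]
  freqs <- freqs_all[keep][ord]
  S <- L * minv  # Cartesian displacement per normal coordinate
  M_tot <- elec_aat$values / c_au + nuc_aat$values
  E_mom <- crossprod(S, vib$apt)       # nmode x 3
  M_mom <- crossprod(S, M_tot)         # nmode x 3
  R_au <- rowSums(E_mom * M_mom)
  structure(list(freqs = freqs, rotatory = R_au * vcd_constants$rotatory_au_to_cgs44,
                 rotatory_au = R_au, electric = E_mom, magnetic = M_mom,
                 modes = S, n_modes = length(freqs),
                 method = elec_aat$method),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %s: %d modes\n", x$method, x$n_modes))
  df <- data.frame(freq_cm1 = round(x$freqs, 2),
                   R_1e44_esu2cm2 = round(x$rotatory, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.spectrum_result <- function(x, ...) {
  data.frame(mode = seq_along(x$freqs), freq_cm1 = x$freqs,
             rotatory = x$rotatory)
}

#' Lorentzian-broadened VCD spectrum
#'
#' Sum of Lorentzians centered at the mode frequencies with areas
#' proportional to the rotatory strengths.
#'
#' @param result a `spectrum_result`.
#' @param fwhm full width at half maximum in cm^-1 (default 8.06573
#'   = 1e-3 eV).
#' @param grid wavenumber grid; defaults to covering all modes with a
#'   margin.
#' @return data.frame with `wavenumber` and `intensity` columns.
#' @export
lorentzian_spectrum <- function(result, fwhm = 8.06573, grid = NULL) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (is.null(grid)) {
    lo <- max(0, min(result$freqs) - 20 * fwhm)
    hi <- max(result$freqs) + 20 * fwhm
    grid <- seq(lo, hi, length.out = 4000)
  }
  gam <- fwhm / 2
  intensity <- numeric(length(grid))
  for (n in seq_along(result$freqs)) {
    intensity <- intensity + result$rotatory[n] * (gam / pi) /
      ((grid - result$freqs[n])^2 + gam^2)
  }
  data.frame(wavenumber = grid, intensity = intensity)
}

#' Plot a VCD spectrum
#'
#' @param result a `spectrum_result`.
#' @param fwhm linewidth passed to [lorentzian_spectrum()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_vcd_spectrum <- function(result, fwhm = 8.06573) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- lorentzian_spectrum(result, fwhm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)),
                  y = expression(Delta * epsilon ~ "(arb. units)"),
                  title = paste("VCD spectrum,", result$method))
}

# ---- experimental HF-level Hessian/APT generator ---------------------------

#' Finite-difference HF Hessian and APT (experimental)
#'
#' Convenience generator for end-to-end demonstrations: central-difference
#' second derivatives of the RHF energy and first derivatives of the RHF
#' dipole moment.  Not intended for production force fields.
#'
#' @param mol a [molecule()].
#' @param basis basis name.
#' @param h displacement step (bohr).
#' @return A [vibrational_data()].
#' @export
fd_hessian_apt <- function(mol, basis, h = 5e-3) {
  mol <- shift_to_com(mol)
  n3 <- 3 * nrow(mol$coords)
  energy_dipole <- function(coords) {
    m <- mol; m$coords <- coords
    ints <- compute_integrals(m, basis, at_com = FALSE)
    scf <- run_rhf(m, ints, conv = 1e-11)
    dip <- cpp_dipole(ints$basis, c(0, 0, 0))
    mu_e <- -c(sum(scf$D * dip$x), sum(scf$D * dip$y), sum(scf$D * dip$z))
    mu_n <- colSums(m$coords * m$charges)
    list(E = scf$E_scf, mu = mu_e + mu_n)
  }
  disp <- function(i, s) {
    x <- mol$coords
    x[(i - 1) %/% 3 + 1, (i - 1) %% 3 + 1] <-
      x[(i - 1) %/% 3 + 1, (i - 1) %% 3 + 1] + s * h
    x
  }
  E0 <- energy_dipole(mol$coords)$E
  plus <- lapply(seq_len(n3), function(i) energy_dipole(disp(i, +1)))
  minus <- lapply(seq_len(n3), function(i) energy_dipole(disp(i, -1)))
  apt <- t(vapply(seq_len(n3), function(i) (plus[[i]]$mu - minus[[i]]$mu) / (2 * h),
                  numeric(3)))
  H <- matrix(0, n3, n3)
  for (i in seq_len(n3)) H[i, i] <- (plus[[i]]$E - 2 * E0 + minus[[i]]$E) / h^2
  for (i in seq_len(n3 - 1)) for (j in seq((i + 1), n3)) {
    epp <- energy_dipole({ x <- disp(i, +1); x[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] <- x[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] + h; x })$E
    emm <- energy_dipole({ x <- disp(i, -1); x[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] <- x[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] - h; x })$E
    H[i, j] <- H[j, i] <- (epp - 2 * E0 + emm - H[i, i] * h^2 - H[j, j] * h^2) / (2 * h^2)
  }
  vibrational_data(H, apt, mol$masses)
}
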
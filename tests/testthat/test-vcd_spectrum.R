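test_that("nuclear AAT has the Levi-Civita structure", {
  mol <- fixture_geometry("water_c2v")
  J <- nuclear_aat(mol)
  for (at in 1:3) {
    blk <- J$values[(at - 1) * 3 + 1:3, ]
    expect_lt(max(abs(blk + t(blk))), 1e-14)  # antisymmetric in (alpha, beta)
  }
  # atom at the origin contributes nothing
  he <- fixture_geometry("he")
  expect_equal(max(abs(nuclear_aat(he)$values)), 0)
})

test_that("matrix files are shape-checked", {
  f <- tempfile()
  writeLines(apply(matrix(round(rnorm(81), 3), 9, 9), 1, paste, collapse = " "), f)
  m <- read_matrix_file(f, 9, 9)
  expect_equal(dim(m), c(9, 9))
  expect_error(read_matrix_file(f, 12, 9), "expected 12")
  g <- tempfile()
  writeLines(apply(matrix(1:27 / 10, 9, 3), 1, paste, collapse = " "), g)
  expect_equal(dim(read_matrix_file(g, 9, 3)), c(9, 3))
  expect_error(vibrational_data(matrix(0, 8, 8), matrix(0, 9, 3),
                                rep(1, 3)), "Hessian must be")
})

test_that("a synthetic one-mode system reproduces the closed-form rotatory strength", {
  # single atom, hand-set diagonal Hessian and tensors: R follows in closed
  # form from the contraction definitions
  mol <- molecule("H", matrix(0, 1, 3))
  k <- 0.04
  H <- diag(c(k, 1e-9, 1e-9))  # one real mode along x, two null modes
  apt <- rbind(c(0.3, 0, 0), c(0, 0, 0), c(0, 0, 0))
  vib <- vibrational_data(H, apt, mol$masses)
  elec <- vcdci:::new_aat(rbind(c(0.2, 0, 0), 0, 0), "full", "HF", 0L, mol)
  nuc <- vcdci:::new_aat(matrix(0, 3, 3), "full", "nuclear", 0L, mol)
  sp <- rotatory_strengths(elec, nuc, vib, zero_cut = 5, project_tr = FALSE)
  expect_equal(sp$n_modes, 1)
  amu <- vcd_constants$amu_to_me
  minv <- 1 / sqrt(mol$masses[1] * amu)
  R_expected <- (minv * 0.3) * (minv * 0.2 / vcd_constants$fine_structure_c) *
    vcd_constants$rotatory_au_to_cgs44
  expect_equal(sp$rotatory, R_expected, tolerance = 1e-12)
})

test_that("achiral planar molecule has vanishing rotatory strengths", {
  mol <- fixture_geometry("water_c2v")
  vib <- memo("water_vib", function() fd_hessian_apt(mol, "6-31G"))
  elec <- water_cid_aat()
  sp <- rotatory_strengths(elec, nuclear_aat(mol), vib)
  expect_equal(sp$n_modes, 3)
  expect_gt(min(sp$freqs), 1000)  # real vibrations of a bound molecule
  expect_lt(max(abs(sp$rotatory)), 1e-8)
})

test_that("mirror-image geometries flip every rotatory strength exactly", {
  # reflect a chiral arrangement through x -> -x and transform the
  # Hessian/APT/AAT consistently: rotatory strengths change sign exactly
  set.seed(10)
  mol <- fixture_geometry("h2_dimer")
  n3 <- 12
  Hh <- crossprod(matrix(rnorm(n3^2), n3)) / 10
  apt <- matrix(rnorm(n3 * 3), n3, 3)
  aat <- matrix(rnorm(n3 * 3), n3, 3)
  refl <- function(M_cart, axis_sign_row, axis_sign_col) {
    Dr <- diag(rep(axis_sign_row, 4)); Dc <- diag(axis_sign_col)
    list(r = Dr, c = Dc)
  }
  sx <- c(-1, 1, 1)        # polar vectors under x-reflection
  sx_ax <- c(1, -1, -1)    # axial vectors under x-reflection
  Dr <- diag(rep(sx, 4))
  mol2 <- mol; mol2$coords[, 1] <- -mol2$coords[, 1]
  Hh2 <- Dr %*% Hh %*% Dr
  apt2 <- Dr %*% apt %*% diag(sx)
  aat2 <- Dr %*% aat %*% diag(sx_ax)
  mk <- function(m, a) vcdci:::new_aat(a, "full", "CID", 0L, m)
  sp1 <- rotatory_strengths(mk(mol, aat), nuclear_aat(shift_to_com(mol)),
                            vibrational_data(Hh, apt, mol$masses))
  sp2 <- rotatory_strengths(mk(mol2, aat2), nuclear_aat(shift_to_com(mol2)),
                            vibrational_data(Hh2, apt2, mol$masses))
  expect_equal(sort(sp1$freqs), sort(sp2$freqs), tolerance = 1e-10)
  expect_equal(sp1$rotatory, -sp2$rotatory, tolerance = 1e-8)
})

test_that("Lorentzian broadening preserves areas and is linear", {
  mol <- molecule("H", matrix(0, 1, 3))
  sp <- structure(list(freqs = c(1000, 1500), rotatory = c(2, -1),
                       n_modes = 2, method = "test"),
                  class = "spectrum_result")
  g1 <- lorentzian_spectrum(sp, fwhm = 8.06573,
                            grid = seq(500, 2000, length.out = 20001))
  # isolated peak area ~ rotatory strength
  near <- g1$wavenumber > 800 & g1$wavenumber < 1200
  area <- sum(g1$intensity[near]) * diff(g1$wavenumber[1:2])
  expect_equal(area, 2, tolerance = 0.02)
  # doubling the width halves the peak height, same area
  g2 <- lorentzian_spectrum(sp, fwhm = 2 * 8.06573,
                            grid = seq(500, 2000, length.out = 20001))
  expect_equal(max(g2$intensity) / max(g1$intensity), 0.5, tolerance = 0.01)
  # zero-strength mode contributes nothing
  sp0 <- sp; sp0$rotatory <- c(2, 0)
  spz <- sp; spz$rotatory <- c(2, -1e-300)
  gz <- lorentzian_spectrum(sp0, grid = g1$wavenumber)
  expect_equal(max(abs(gz$intensity[g1$wavenumber > 1400] -
                         0 * gz$intensity[g1$wavenumber > 1400])),
               max(abs(gz$intensity[g1$wavenumber > 1400])))
  expect_lt(max(abs(gz$intensity[abs(g1$wavenumber - 1500) < 20])), 0.02)
})
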
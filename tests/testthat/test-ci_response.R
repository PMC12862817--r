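test_that("analytic CI energy gradient matches finite differences", {
  w <- water_scf()
  ci <- water_cid()
  la <- 3  # totally symmetric O-z displacement (nonzero gradient)
  dints <- compute_derivative_integrals(w$ints, la)
  resp <- solve_cphf_nuclear(w$scf, dints, n_frozen = 1)
  dham <- build_derivative_hamiltonian(w$so, w$scf, resp, dints)
  dc <- solve_ci_response(ci, dham, tol = 1e-12)
  h <- 1e-6
  solve_at <- function(sgn) {
    m <- w$mol; m$coords[1, 3] <- m$coords[1, 3] + sgn * h
    ints <- compute_integrals(m, "6-31G", at_com = FALSE)
    scf <- run_rhf(m, ints, 1e-13, orb_conv = 1e-14)
    solve_ci(to_spin_orbital(scf), "CID", n_frozen = 1, tol = 1e-13)
  }
  cp <- solve_at(1); cm <- solve_at(-1)
  dE_fd <- (cp$E_tot - cm$E_tot) / (2 * h)
  denuc <- {
    f <- function(x) {
      m <- w$mol; m$coords[1, 3] <- m$coords[1, 3] + x
      vcdci:::nuclear_repulsion(m)
    }
    (f(h) - f(-h)) / (2 * h)
  }
  expect_lt(abs(dc$dE_elec + denuc - dE_fd), 1e-7)
})

test_that("perturbed coefficients match FD re-solves in the same orbital gauge", {
  w <- water_scf()
  ci <- solve_ci(w$so, "CISD", n_frozen = 1, tol = 1e-12)
  la <- 2
  dints <- compute_derivative_integrals(w$ints, la)
  resp <- solve_cphf_nuclear(w$scf, dints, n_frozen = 1)
  dham <- build_derivative_hamiltonian(w$so, w$scf, resp, dints)
  dc <- solve_ci_response(ci, dham, tol = 1e-12)
  expect_lt(dc$resid, 1e-9)
  h <- 1e-6
  solve_imposed <- function(sgn) {
    m <- w$mol
    m$coords[dints$atom, dints$dim] <- m$coords[dints$atom, dints$dim] + sgn * h
    ii <- compute_integrals(m, "6-31G", at_com = FALSE)
    Cp <- w$scf$C %*% (diag(ncol(w$scf$C)) + sgn * h * resp$U_spatial)
    Ct <- Cp %*% vcdci:::sym_inv_sqrt(crossprod(Cp, ii$S %*% Cp))
    vcdci:::fd_solve_coefficients(vcdci:::so_build(Ct, ii, w$scf$n_occ),
                                  "CISD", 1, 1e-13,
                                  list(c1 = ci$c1, c2 = ci$c2))
  }
  cp <- solve_imposed(1); cm <- solve_imposed(-1)
  expect_lt(max(abs((cp$c2 - cm$c2) / (2 * h) - dc$dc2)), 1e-6)
  expect_lt(max(abs((cp$c1 - cm$c1) / (2 * h) - dc$dc1)), 1e-6)
})

test_that("magnetic response is purely imaginary with zero energy derivative", {
  w <- water_scf()
  ci <- water_cid()
  resp <- solve_cphf_magnetic(w$scf, 2, n_frozen = 1)
  dham <- build_derivative_hamiltonian(w$so, w$scf, resp)
  # the stored derivative Hamiltonian of the imaginary perturbation is real
  # antisymmetric (i times it is Hermitian)
  expect_lt(max(abs(dham$dh + t(dham$dh))), 1e-10)
  dc <- solve_ci_response(ci, dham, tol = 1e-11)
  expect_identical(dc$dE_elec, 0)
  expect_identical(dc$reality, "imaginary")
  # CID level: singles response identically absent
  expect_equal(max(abs(dc$dc1)), 0)
})

test_that("nuclear derivative Hamiltonian is Hermitian in its stored form", {
  w <- water_scf()
  dints <- compute_derivative_integrals(w$ints, 5)
  resp <- solve_cphf_nuclear(w$scf, dints, n_frozen = 0)
  dham <- build_derivative_hamiltonian(w$so, w$scf, resp, dints)
  expect_lt(max(abs(dham$dh - t(dham$dh))), 1e-9)
  expect_lt(max(abs(dham$dg - aperm(dham$dg, c(3, 4, 1, 2)))), 1e-9)
})

test_that("MP2 derivative amplitudes are consistent at the tensor level", {
  # the MP2 response is validated end to end: analytic vs mixed-FD AAT on
  # the hydrogen-molecule dimer (every dc2 enters the contraction)
  mol <- fixture_geometry("h2_dimer")
  an <- aat_analytic(mol, "6-31G", "MP2", frozen_core = FALSE,
                     normalization = "full", conv = 1e-11)
  mx <- mixed_fd_aat(mol, "6-31G", "MP2", frozen_core = FALSE,
                     normalization = "full")
  expect_lt(max(abs(an$values - mx$values)), 1e-7)
})
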
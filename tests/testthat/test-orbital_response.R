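test_that("nuclear CPHF satisfies the overlap relation and matches FD orbitals", {
  w <- water_scf()
  h <- 1e-5
  for (la in c(1, 5)) {
    dints <- compute_derivative_integrals(w$ints, la)
    resp <- solve_cphf_nuclear(w$scf, dints, n_frozen = 0)
    # orthonormality: U + t(U) + S_chi = 0 (see vignette for the sign
    # convention of S_chi)
    expect_lt(max(abs(resp$U_spatial + t(resp$U_spatial) + resp$S_spatial)),
              1e-9)
    # FD-orbital oracle on the (unique) virtual-occupied block
    atom <- dints$atom; d <- dints$dim
    Ms <- lapply(c(1, -1), function(sgn) {
      m <- w$mol; m$coords[atom, d] <- m$coords[atom, d] + sgn * h
      ints <- compute_integrals(m, "6-31G", at_com = FALSE)
      scf <- run_rhf(m, ints, 1e-13, orb_conv = 1e-13)
      S01 <- cross_overlap(w$ints$basis, ints$basis)
      M <- crossprod(w$scf$C, S01 %*% scf$C)
      for (p in seq_len(ncol(M))) if (M[p, p] < 0) M[, p] <- -M[, p]
      M
    })
    A_fd <- (Ms[[1]] - Ms[[2]]) / (2 * h)
    U_fd <- A_fd - t(resp$halfS_mo)
    n <- ncol(w$scf$C); o <- seq_len(w$scf$n_occ); v <- setdiff(seq_len(n), o)
    expect_lt(max(abs(U_fd[v, o] - resp$U_spatial[v, o])), 1e-6)
  }
})

test_that("magnetic CPHF is symmetric-imaginary and matches the complex-SCF oracle", {
  w <- water_scf()
  hB <- 1e-5
  resp <- solve_cphf_magnetic(w$scf, 3, n_frozen = 0)
  u <- resp$u_spatial
  expect_lt(max(abs(u - t(u))), 1e-12)   # anti-Hermitian purely imaginary U
  expect_equal(max(abs(resp$S_chi)), 0)
  n <- ncol(w$scf$C); o <- seq_len(w$scf$n_occ); v <- setdiff(seq_len(n), o)
  expect_equal(max(abs(u[o, o])), 0)     # all-electron: oo/vv blocks zero
  expect_equal(max(abs(u[v, v])), 0)
  fp <- run_rhf_field(w$ints, c(0, 0, hB), w$scf$C, conv = 1e-13,
                      orb_conv = 1e-14)
  u_fd <- Im(crossprod(w$scf$C, w$ints$S %*% fp$C)) / hB
  expect_lt(max(abs(u_fd[v, o] - u[v, o])), 1e-6)
  # He atom: s functions only carry no magnetic coupling
  he <- fixture_geometry("he")
  ih <- compute_integrals(he, "6-31G")
  sh <- run_rhf(he, ih, 1e-13)
  expect_equal(max(abs(solve_cphf_magnetic(sh, 1)$u)), 0)
})

test_that("noncanonical convention survives exact orbital degeneracy", {
  # Ne atom: degenerate occupied p shell; the -S/2 convention avoids
  # orbital-energy denominators within the occupied space
  ne <- molecule("Ne", matrix(0, 1, 3))
  ints <- compute_integrals(ne, "6-31G")
  scf <- run_rhf(ne, ints, 1e-12)
  expect_lt(abs(scf$eps[3] - scf$eps[4]), 1e-9)  # 2p degeneracy
  dints <- compute_derivative_integrals(ints, 1)
  resp <- solve_cphf_nuclear(scf, dints, n_frozen = 0)
  expect_true(all(is.finite(resp$U_spatial)))
})

test_that("frozen-core toggle with n_frozen = 0 is bit-identical", {
  w <- water_scf()
  dints <- compute_derivative_integrals(w$ints, 2)
  r0 <- solve_cphf_nuclear(w$scf, dints, n_frozen = 0)
  r1 <- solve_cphf_nuclear(w$scf, dints, n_frozen = 0)
  expect_identical(r0$U, r1$U)
  # with a frozen core only the core/active-occupied block changes
  rf <- solve_cphf_nuclear(w$scf, dints, n_frozen = 1)
  n <- ncol(w$scf$C); o <- 2:w$scf$n_occ
  expect_equal(rf$U_spatial[6:n, 1:5], r0$U_spatial[6:n, 1:5])
})
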
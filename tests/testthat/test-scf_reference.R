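test_that("RHF reference satisfies its defining identities", {
  w <- water_scf()
  scf <- w$scf; S <- w$ints$S
  # idempotency and orthonormality
  expect_lt(max(abs(scf$D %*% S %*% scf$D - 2 * scf$D)), 1e-8)
  expect_lt(max(abs(crossprod(scf$C, S %*% scf$C) - diag(w$ints$nbf))), 1e-10)
  # Brillouin: virtual-occupied Fock block vanishes
  F <- w$ints$h + vcdci:::fock_2e(w$ints$eri, scf$D)
  Fmo <- crossprod(scf$C, F %*% scf$C)
  o <- seq_len(scf$n_occ); v <- setdiff(seq_len(w$ints$nbf), o)
  expect_lt(max(abs(Fmo[v, o])), 1e-8)
  expect_lt(max(abs(Fmo - diag(diag(Fmo)))), 1e-8)  # canonical orbitals
  # deterministic phases: rerun from scratch gives identical coefficients
  scf2 <- run_rhf(w$mol, w$ints, conv = 1e-13, orb_conv = 1e-13)
  expect_lt(max(abs(scf2$C - scf$C)), 1e-7)
})

test_that("spin-orbital store is antisymmetric and energy-consistent", {
  w <- water_scf()
  g <- w$so$g
  set.seed(4)
  for (r in 1:10) {
    id <- sample(w$so$nso, 4, TRUE)
    v <- g[id[1], id[2], id[3], id[4]]
    expect_equal(v, -g[id[1], id[2], id[4], id[3]])
    expect_equal(v, -g[id[2], id[1], id[3], id[4]])
  }
  # spin orthogonality: an odd number of beta spins cannot pair up
  expect_equal(g[1, 1, 1, 2], 0)
  expect_equal(g[2, 2, 2, 1], 0)
  # electronic energy from the spin-orbital store equals the SCF energy
  occ <- seq_len(w$so$n_occ_so)
  e1 <- sum(diag(w$so$h)[occ])
  e2 <- 0
  for (i in occ) for (j in occ) e2 <- e2 + 0.5 * g[i, j, i, j]
  expect_equal(e1 + e2, w$scf$E_elec, tolerance = 1e-10)
  # round trip: back-transform h to the AO basis
  Cinv <- solve(w$scf$C)
  h_ao <- t(Cinv) %*% crossprod(w$scf$C, w$ints$h %*% w$scf$C) %*% Cinv
  expect_lt(max(abs(h_ao - w$ints$h)), 1e-9)
})

test_that("spin-orbital MP2 equals the closed-shell spatial-orbital value", {
  w <- water_scf()
  mp <- mp2_coefficients(w$so, 0)
  # independent spatial-orbital oracle: E2 = sum (ia|jb)[2(ia|jb)-(ib|ja)]/D
  C <- w$scf$C; eps <- w$scf$eps; nocc <- w$scf$n_occ; n <- w$ints$nbf
  mo <- vcdci:::ao2mo_eri(w$ints$eri, C)
  e2 <- 0
  for (i in 1:nocc) for (j in 1:nocc)
    for (a in (nocc + 1):n) for (b in (nocc + 1):n) {
      iajb <- mo[i, a, j, b]; ibja <- mo[i, b, j, a]
      e2 <- e2 + iajb * (2 * iajb - ibja) / (eps[i] + eps[j] - eps[a] - eps[b])
    }
  expect_equal(mp$E_corr, e2, tolerance = 1e-10)
  # He in a basis with virtuals still has negative denominators (Aufbau)
  expect_lt(max(mp$c2), Inf)
})
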
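# The assembly engine is locked against a brute-force determinant-algebra
# oracle: every projected class of (one-body operator applied to the CI
# vector) and the full bilinear form are compared on random tensors,
# including frozen-core (core-hole) channels.

brute_setup <- function(nso, nel, nfz) {
  No <- nel; Nv <- nso - nel
  act <- (nfz + 1):No
  list(nso = nso, nel = nel, nfz = nfz, No = No, Nv = Nv, noa = length(act),
       space = det_space(nel, nso, nfz, "CISD"))
}

fake_ci <- function(st, c1, c2) {
  list(ham = list(n_occ_so = st$nel, n_frozen_so = st$nfz, nv = st$Nv,
                  no = st$noa),
       c1 = c1, c2 = c2, n_frozen = st$nfz / 2)
}

test_that("operator classes match the brute-force determinant algebra", {
  set.seed(8)
  st <- brute_setup(10, 6, 2)
  c1 <- matrix(rnorm(st$noa * st$Nv), st$noa, st$Nv)
  c2 <- random_c2(st$noa, st$Nv)
  op <- matrix(rnorm(st$nso^2), st$nso)
  ew <- vcdci:::embed_full(fake_ci(st, c1, c2), c1, c2)
  cls <- vcdci:::op_classes(op, 1, ew$c1, ew$c2, st$No, st$Nv)
  wf <- vcdci:::brute_wf_from_tensor(st$space, 1, c1, c2)
  out <- vcdci:::brute_obody_apply(wf, op)
  # reference amplitude
  expect_equal(cls$ref, out[[vcdci:::det_key(1:st$nel)]], tolerance = 1e-12)
  # singles class, including core-hole rows
  for (i in 1:st$No) for (a in (st$No + 1):st$nso) {
    r <- vcdci:::apply_excitation(1:st$nel, i, a)
    amp <- out[[vcdci:::det_key(r$det)]]
    if (is.null(amp)) amp <- 0
    expect_equal(cls$S[i, a - st$No] * r$phase, amp, tolerance = 1e-12)
  }
  # doubles class (spot check including a core hole)
  combos <- rbind(c(1, 3, 7, 8), c(2, 5, 9, 10), c(3, 4, 7, 10), c(5, 6, 8, 9))
  for (r in seq_len(nrow(combos))) {
    i <- combos[r, 1]; j <- combos[r, 2]; a <- combos[r, 3]; b <- combos[r, 4]
    r1 <- vcdci:::apply_annihilation(1:st$nel, i)
    r2 <- vcdci:::apply_annihilation(r1$det, j)
    r3 <- vcdci:::apply_creation(r2$det, b)
    r4 <- vcdci:::apply_creation(r3$det, a)
    amp <- out[[vcdci:::det_key(r4$det)]]
    if (is.null(amp)) amp <- 0
    ph <- r1$phase * r2$phase * r3$phase * r4$phase
    expect_equal(cls$D[i, j, a - st$No, b - st$No] * ph, amp, tolerance = 1e-12)
  }
})

test_that("triples contraction intermediates equal the brute-force overlap", {
  set.seed(9)
  st <- brute_setup(10, 6, 2)
  for (trial in 1:3) {
    c1 <- matrix(rnorm(st$noa * st$Nv), st$noa, st$Nv)
    c2 <- random_c2(st$noa, st$Nv)
    A <- matrix(rnorm(st$nso^2), st$nso)
    Bv <- matrix(rnorm(st$nso^2), st$nso)
    ew <- vcdci:::embed_full(fake_ci(st, c1, c2), c1, c2)
    clsA <- vcdci:::op_classes(A, 1, ew$c1, ew$c2, st$No, st$Nv)
    clsB <- vcdci:::op_classes(Bv, 1, ew$c1, ew$c2, st$No, st$Nv)
    wf <- vcdci:::brute_wf_from_tensor(st$space, 1, c1, c2)
    full <- vcdci:::brute_dot(vcdci:::brute_obody_apply(wf, A),
                              vcdci:::brute_obody_apply(wf, Bv))
    partial <- clsA$ref * clsB$ref + sum(clsA$S * clsB$S) +
      0.25 * sum(clsA$D * clsB$D)
    v <- (st$No + 1):st$nso; o <- 1:st$No
    tt <- sum(vcdci:::TRIPLES_COEF *
                vcdci:::triples_dot(ew$c2, A[v, o], ew$c2, Bv[v, o],
                                    st$No, st$Nv))
    expect_equal(partial + tt, full, tolerance = 1e-10)
  }
})

test_that("X/Y intermediates reproduce the naive O(N^6) contraction", {
  w <- water_scf()
  ci <- water_cid()
  dints <- compute_derivative_integrals(w$ints, 2)
  cphf_R <- solve_cphf_nuclear(w$scf, dints, 1)
  cphf_H <- solve_cphf_magnetic(w$scf, 2, 1)
  bi <- build_intermediates(cphf_H, cphf_R, ci)
  cw <- vcdci:::embed_full(ci, ci$c1, ci$c2)
  No <- cw$No; Nv <- cw$Nv
  expect_equal(dim(bi$X), c(Nv, Nv))
  o <- seq_len(No); v <- No + seq_len(Nv)
  Avo <- vcdci:::aat_op_matrix_R(cphf_R)[v, o]
  uvo <- cphf_H$u[v, o]
  # naive O(N^6): term = -1/2 sum_ijab c+ [ sum_me u[b,m] A[e,m] c_ij^ae ]
  naive <- 0
  for (b in seq_len(Nv)) for (e in seq_len(Nv)) {
    x_be <- sum(uvo[b, ] * Avo[e, ])
    naive <- naive - 0.5 * x_be * sum(cw$c2[, , , b] * cw$c2[, , , e])
  }
  expect_equal(bi$term, naive, tolerance = 1e-12)
  # zero magnetic response implies a vanishing term
  cphf_H0 <- cphf_H; cphf_H0$u <- 0 * cphf_H0$u
  expect_equal(build_intermediates(cphf_H0, cphf_R, ci)$term, 0)
})

test_that("He atom has a vanishing AAT at every level", {
  he <- fixture_geometry("he")
  for (m in c("HF", "MP2", "CID", "CISD")) {
    a <- aat_analytic(he, "6-31G", m, frozen_core = FALSE,
                      normalization = "full", conv = 1e-11)
    expect_lt(max(abs(a$values)), 1e-10)
  }
})

test_that("CISD assembly with zeroed singles reproduces CID bit for bit", {
  w <- water_scf()
  cid <- water_cid()
  cisd <- solve_ci(w$so, "CISD", n_frozen = 1, tol = 1e-12)
  # same doubles, singles channels forced to zero -> identical code path
  cisd_z <- cisd
  cisd_z$c1 <- 0 * cisd_z$c1
  cisd_z$c2 <- cid$c2
  n_coord <- 9
  dints <- lapply(1:2, function(la) compute_derivative_integrals(w$ints, la))
  cphf_R <- lapply(dints, function(d) solve_cphf_nuclear(w$scf, d, 1))
  cphf_H <- lapply(1:3, function(b) solve_cphf_magnetic(w$scf, b, 1))
  zero_resp <- function(chi) structure(
    list(dc1 = 0 * cid$c1, dc2 = 0 * cid$c2, dE_elec = 0, chi = chi,
         reality = "real", resid = 0), class = "ci_response")
  rR <- lapply(1:2, function(i) zero_resp("R"))
  rH <- lapply(1:3, function(i) zero_resp("H"))
  a_cid <- assemble_aat_intermediate(cid, cphf_R, cphf_H, rR, rH, "CID")
  a_cisd <- assemble_aat_intermediate(cisd_z, cphf_R, cphf_H, rR, rH, "CISD")
  expect_identical(a_cid$values, a_cisd$values)
})

test_that("frozen-core with n_frozen = 0 equals the all-electron AAT", {
  mol <- fixture_geometry("h2_dimer")
  a1 <- aat_analytic(mol, "6-31G", "CID", frozen_core = FALSE,
                     normalization = "full", conv = 1e-11)
  a2 <- aat_analytic(mol, "6-31G", "CID", frozen_core = TRUE,
                     normalization = "full", conv = 1e-11)
  # no non-hydrogen atoms: frozen_core = TRUE freezes nothing
  expect_identical(a2$frozen_core, 0L)
  expect_lt(max(abs(a1$values - a2$values)), 1e-12)
})

test_that("normalization data follow the closed forms", {
  w <- water_scf()
  ci <- water_cid()
  # N against the direct norm
  nrm <- sqrt(1 + sum(ci$c1^2) + 0.25 * sum(ci$c2^2))
  fake_resp <- lapply(1:3, function(i) structure(
    list(dc1 = 0 * ci$c1, dc2 = 0 * ci$c2), class = "ci_response"))
  nd0 <- normalization_data(ci, fake_resp)
  expect_equal(nd0$N, 1 / nrm, tolerance = 1e-13)
  expect_equal(nd0$dN_dR, rep(0, 3))
  # all-zero coefficients give N = 1
  hf <- vcdci:::hf_wavefunction(w$so, 1)
  expect_equal(normalization_data(hf, fake_resp)$N, 1)
  # N decreases monotonically as any doubles amplitude grows
  ci_big <- ci; ci_big$c2 <- 1.5 * ci$c2
  expect_lt(normalization_data(ci_big, fake_resp)$N, nd0$N)
  # dN/dR against finite differences of N built from FD coefficients
  h <- 1e-6
  la <- 3
  solve_at <- function(sgn) {
    m <- w$mol; m$coords[1, 3] <- m$coords[1, 3] + sgn * h
    ints <- compute_integrals(m, "6-31G", at_com = FALSE)
    scf <- run_rhf(m, ints, 1e-13, orb_conv = 1e-14)
    solve_ci(to_spin_orbital(scf), "CID", n_frozen = 1, tol = 1e-13)
  }
  cp <- solve_at(1); cm <- solve_at(-1)
  Np <- 1 / sqrt(1 + 0.25 * sum(cp$c2^2)); Nm <- 1 / sqrt(1 + 0.25 * sum(cm$c2^2))
  dints <- compute_derivative_integrals(w$ints, la)
  cphf <- solve_cphf_nuclear(w$scf, dints, 1)
  dham <- build_derivative_hamiltonian(w$so, w$scf, cphf, dints)
  dc <- solve_ci_response(ci, dham, tol = 1e-12)
  nd <- normalization_data(ci, list(dc))
  expect_equal(nd$dN_dR[1], (Np - Nm) / (2 * h), tolerance = 1e-7)
})

test_that("full normalization reduces to the intermediate tensor for HF", {
  he <- fixture_geometry("h2_dimer")
  a_int <- aat_analytic(he, "6-31G", "HF", frozen_core = FALSE,
                        normalization = "intermediate", conv = 1e-11)
  a_full <- aat_analytic(he, "6-31G", "HF", frozen_core = FALSE,
                         normalization = "full", conv = 1e-11)
  expect_equal(a_full$values, a_int$values, tolerance = 1e-14)
})
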
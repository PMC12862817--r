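test_that("determinant space addressing is a bijection with exact phases", {
  sp <- det_space(4, 10, 0, "CISD")
  expect_equal(nrow(sp$dets), 1 + 4 * 6 + choose(4, 2) * choose(6, 2))
  # round-trip a random packed vector through the sorted-determinant form
  set.seed(5)
  pk <- vcdci:::ci_packing(4, 6, "CISD")
  v <- rnorm(pk$len)
  cv <- vcdci:::unpack_ci(pk, v)
  dv <- vcdci:::tensor_to_detvec(sp, cv$c0, cv$c1, cv$c2)
  back <- vcdci:::detvec_to_tensor(sp, dv)
  expect_equal(back$c0, cv$c0)
  expect_equal(back$c1, cv$c1)
  expect_equal(back$c2, cv$c2)
  # no frozen index appears in any excitation label
  spf <- det_space(4, 10, 2, "CISD")
  labs <- spf$labels[-1]
  expect_true(all(vapply(labs, function(l) all(c(l$i, l$j) > 2), logical(1))))
})

test_that("contraction sigma equals the dense Slater-Condon Hamiltonian", {
  set.seed(6)
  for (cfg in list(list(8, 4, 0, "CISD", TRUE), list(8, 4, 0, "CID", TRUE),
                   list(8, 4, 2, "CISD", TRUE), list(8, 4, 2, "CISD", FALSE))) {
    nso <- cfg[[1]]; nel <- cfg[[2]]; nfz <- cfg[[3]]
    level <- cfg[[4]]; herm <- cfg[[5]]
    h <- matrix(rnorm(nso^2), nso)
    h <- if (herm) (h + t(h)) / 2 else (h - t(h)) / 2
    g <- random_g(nso, herm)
    space <- det_space(nel, nso, nfz, level)
    H <- vcdci:::cpp_hci_dense(space$dets, h, as.vector(g))
    ham <- vcdci:::ci_hamiltonian(h, g, nel, nfz)
    pk <- vcdci:::ci_packing(ham$no, ham$nv, level)
    v <- rnorm(pk$len)
    cv <- vcdci:::unpack_ci(pk, v)
    s <- vcdci:::sigma_cisd(ham, vcdci:::ci_fock(ham), vcdci:::ci_e0(ham),
                            cv$c0, cv$c1, cv$c2, level)
    sv <- vcdci:::pack_ci(pk, s$s0, s$s1, s$s2)
    dv <- vcdci:::tensor_to_detvec(space, cv$c0,
                                   if (level == "CISD") cv$c1 else NULL, cv$c2)
    st <- vcdci:::detvec_to_tensor(space, as.vector(H %*% dv))
    expect_lt(max(abs(sv - vcdci:::pack_ci(pk, st$c0, st$c1, st$c2))), 1e-12)
  }
})

test_that("two-electron CISD equals dense full CI", {
  m2 <- fixture_geometry("h2")
  i2 <- compute_integrals(m2, "6-31G")
  scf <- run_rhf(m2, i2, 1e-13)
  so <- to_spin_orbital(scf)
  ci <- solve_ci(so, "CISD", tol = 1e-12)
  dets <- t(combn(so$nso, 2))
  H <- vcdci:::cpp_hci_dense(dets, so$h, as.vector(so$g))
  efci <- min(eigen((H + t(H)) / 2, symmetric = TRUE)$values) + so$enuc
  expect_equal(ci$E_tot, efci, tolerance = 1e-10)
})

test_that("CISD is variationally below CID; coefficients are antisymmetric", {
  w <- water_scf()
  cid <- water_cid()
  cisd <- solve_ci(w$so, "CISD", n_frozen = 1, tol = 1e-11)
  expect_lt(cisd$E_tot, cid$E_tot)
  expect_equal(cid$c2, -aperm(cid$c2, c(2, 1, 3, 4)))
  expect_equal(cid$c2, -aperm(cid$c2, c(1, 2, 4, 3)))
  expect_equal(cid$c0, 1)
  # frozen-core with n_frozen = 0 equals the all-electron solve
  cid0a <- solve_ci(w$so, "CID", n_frozen = 0, tol = 1e-12)
  # (identical code path; equality of energies across restarts)
  cid0b <- solve_ci(w$so, "CID", n_frozen = 0, tol = 1e-12)
  expect_equal(cid0a$E_tot, cid0b$E_tot, tolerance = 1e-11)
})

test_that("MP2 coefficients follow the canonical closed form", {
  w <- water_scf()
  mp <- mp2_coefficients(w$so, 1)
  ham <- mp$ham
  o <- seq_len(ham$no); v <- ham$no + seq_len(ham$nv)
  eps <- Re(diag(vcdci:::ci_fock(ham)))
  den <- outer(outer(eps[o], eps[o], "+"), outer(eps[v], eps[v], "+"), "-")
  expect_true(all(den < 0))   # gapped closed-shell system
  expect_equal(mp$c2 * den, ham$g[o, o, v, v], tolerance = 1e-12)
  expect_equal(mp$E_corr, 0.25 * sum(ham$g[o, o, v, v] * mp$c2),
               tolerance = 1e-12)
})
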
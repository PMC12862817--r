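test_that("nonorthogonal CI overlap reduces to orthonormal Slater-Condon values", {
  d <- dimer_scf()
  ci <- solve_ci(d$so, "CISD", 0, tol = 1e-11)
  space <- det_space(d$so$n_occ_so, d$so$nso, 0, "CISD")
  vec <- vcdci:::tensor_to_detvec(space, 1, ci$c1, ci$c2)
  n <- d$so$nso
  # identical orthonormal bases: overlap = unnormalized self-overlap
  ident <- diag(n / 2)
  Smo <- vcdci:::so_expand_1e(ident)
  ov <- ci_overlap(space$dets, vec + 0i, vec + 0i, Smo)
  expect_equal(Re(ov), 1 + sum(ci$c1^2) + 0.25 * sum(ci$c2^2),
               tolerance = 1e-11)
  expect_equal(Im(ov), 0)
  # cross-geometry machinery at zero displacement reproduces the same value
  Smo2 <- vcdci:::so_expand_1e(crossprod(d$scf$C, d$ints$S %*% d$scf$C))
  ov2 <- ci_overlap(space$dets, vec + 0i, vec + 0i, Smo2)
  expect_equal(Re(ov2), Re(ov), tolerance = 1e-10)
})

test_that("the two FD oracles agree with each other and with the analytic AAT", {
  mol <- fixture_geometry("h2_dimer")
  an <- aat_analytic(mol, "6-31G", "CISD", frozen_core = FALSE,
                     normalization = "intermediate", conv = 1e-11)
  mx <- mixed_fd_aat(mol, "6-31G", "CISD", frozen_core = FALSE,
                     normalization = "intermediate")
  ff <- full_fd_aat(mol, "6-31G", "CISD", frozen_core = FALSE,
                    normalization = "intermediate")
  expect_lt(max(abs(mx$values - ff$values)), 1e-7)
  expect_lt(max(abs(an$values - mx$values)), 1e-7)
  expect_lt(max(abs(an$values - ff$values)), 1e-7)
})

test_that("full normalization carries through both oracles", {
  mol <- fixture_geometry("h2_dimer")
  an <- aat_analytic(mol, "6-31G", "CID", frozen_core = FALSE,
                     normalization = "full", conv = 1e-11)
  ff <- full_fd_aat(mol, "6-31G", "CID", frozen_core = FALSE,
                    normalization = "full")
  expect_lt(max(abs(an$values - ff$values)), 1e-7)
})

test_that("He atom gives a zero tensor to FD noise", {
  he <- fixture_geometry("he")
  ff <- full_fd_aat(he, "6-31G", "CISD", frozen_core = FALSE)
  expect_lt(max(abs(ff$values)), 1e-10)
})

test_that("central differences converge at second order", {
  # at HF level the full-FD oracle is cheap; enlarge the steps so the O(h^2)
  # truncation dominates the numerical floor and compare against analytic
  mol <- fixture_geometry("h2_dimer")
  an <- aat_analytic(mol, "6-31G", "HF", frozen_core = FALSE,
                     normalization = "intermediate", conv = 1e-12)
  devs <- vapply(c(2e-2, 1e-2), function(h) {
    ff <- full_fd_aat(mol, "6-31G", "HF", frozen_core = FALSE, h_R = h,
                      h_B = h, normalization = "intermediate")
    max(abs(ff$values - an$values))
  }, numeric(1))
  ratio <- devs[1] / devs[2]
  expect_gt(ratio, 2.8)  # O(h^2): halving the step shrinks the error ~4x
  expect_lt(ratio, 5.5)
})
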
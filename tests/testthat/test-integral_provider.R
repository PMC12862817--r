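test_that("AO integral matrices have the required structure", {
  w <- water_scf()
  S <- w$ints$S
  expect_lt(max(abs(S - t(S))), 1e-14)
  expect_gt(min(eigen(S, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(S)), rep(1, w$ints$nbf), tolerance = 1e-12)
  for (b in 1:3)
    expect_lt(max(abs(w$ints$ell[[b]] + t(w$ints$ell[[b]]))), 1e-12)
  e <- w$ints$eri
  set.seed(3)
  for (r in 1:12) {
    id <- sample(w$ints$nbf, 4, TRUE)
    v <- e[id[1], id[2], id[3], id[4]]
    expect_equal(v, e[id[2], id[1], id[3], id[4]])
    expect_equal(v, e[id[3], id[4], id[1], id[2]])
    expect_equal(v, e[id[1], id[2], id[4], id[3]])
  }
  # s-only atom at the origin carries no angular momentum
  he <- compute_integrals(fixture_geometry("he"), "6-31G")
  for (b in 1:3) expect_equal(max(abs(he$ell[[b]])), 0)
})

test_that("overlap elements match independent numerical quadrature", {
  m2 <- fixture_geometry("h2")
  i2 <- compute_integrals(m2, "6-31G")
  bs <- i2$basis
  aoval <- function(i, x, y, z) {
    l <- bs$l[i, ]; A <- bs$center[i, ]
    r2 <- (x - A[1])^2 + (y - A[2])^2 + (z - A[3])^2
    v <- 0
    for (k in seq_along(bs$expo[[i]]))
      v <- v + bs$coef[[i]][k] * exp(-bs$expo[[i]][k] * r2)
    (x - A[1])^l[1] * (y - A[2])^l[2] * (z - A[3])^l[3] * v
  }
  g <- seq(-8, 8, length.out = 121); h <- g[2] - g[1]
  G <- expand.grid(x = g, y = g, z = g)
  f1 <- aoval(1, G$x, G$y, G$z); f3 <- aoval(3, G$x, G$y, G$z)
  expect_equal(sum(f1 * f3) * h^3, i2$S[1, 3], tolerance = 1e-5)
})

test_that("derivative integrals match finite differences of the integrals", {
  mol <- fixture_geometry("h2_dimer")
  ints <- compute_integrals(mol, "6-31G")
  h <- 1e-5
  for (la in c(2, 7)) {
    dint <- compute_derivative_integrals(ints, la)
    expect_lt(max(abs(dint$S_R - dint$halfS - t(dint$halfS))), 1e-14)
    atom <- dint$atom; d <- dint$dim
    pm <- lapply(c(1, -1), function(sgn) {
      m <- mol; m$coords[atom, d] <- m$coords[atom, d] + sgn * h
      compute_integrals(m, "6-31G", at_com = FALSE)
    })
    expect_lt(max(abs((pm[[1]]$S - pm[[2]]$S) / (2 * h) - dint$S_R)), 1e-7)
    expect_lt(max(abs((pm[[1]]$h - pm[[2]]$h) / (2 * h) - dint$h_R)), 1e-7)
    expect_lt(max(abs((pm[[1]]$eri - pm[[2]]$eri) / (2 * h) - dint$eri_R)), 1e-7)
  }
  # translational invariance of the basis: sum_lambda S^R = 0
  for (d in 1:3) {
    tot <- 0
    for (atom in seq_len(nrow(mol$coords)))
      tot <- tot + compute_derivative_integrals(ints, (atom - 1) * 3 + d)$S_R
    expect_lt(max(abs(tot)), 1e-12)
  }
})

test_that("half-derivative overlaps are local to the displaced atom", {
  w <- water_scf()
  dint <- compute_derivative_integrals(w$ints, 4)  # H atom 2, x
  on_atom <- w$ints$basis$atom == 2
  expect_equal(max(abs(dint$halfS[!on_atom, ])), 0)
})

test_that("aug-cc-pVDZ (with d functions) builds and passes basic checks", {
  he <- fixture_geometry("h2")
  ints <- compute_integrals(he, "aug-cc-pVDZ")
  expect_equal(ints$nbf, 18)
  expect_equal(unname(diag(ints$S)), rep(1, 18), tolerance = 1e-10)
  expect_gt(min(eigen(ints$S, symmetric = TRUE)$values), 0)
  o <- compute_integrals(fixture_geometry("water_c2v"), "aug-cc-pVDZ")
  expect_equal(unname(diag(o$S)), rep(1, o$nbf), tolerance = 1e-10)
  expect_lt(max(abs(o$ell[[3]] + t(o$ell[[3]]))), 1e-11)
})
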
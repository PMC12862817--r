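# Lazily built, cached reference systems shared across test files.
.sys_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.sys_cache[[key]])) .sys_cache[[key]] <- builder()
  .sys_cache[[key]]
}

water_scf <- function() memo("water_scf", function() {
  mol <- fixture_geometry("water_c2v")
  ints <- compute_integrals(mol, "6-31G")
  scf <- run_rhf(mol, ints, conv = 1e-13, orb_conv = 1e-13)
  list(mol = mol, ints = ints, scf = scf, so = to_spin_orbital(scf))
})

dimer_scf <- function() memo("dimer_scf", function() {
  mol <- fixture_geometry("h2_dimer")
  ints <- compute_integrals(mol, "6-31G")
  scf <- run_rhf(mol, ints, conv = 1e-13, orb_conv = 1e-13)
  list(mol = mol, ints = ints, scf = scf, so = to_spin_orbital(scf))
})

water_cid <- function() memo("water_cid", function() {
  w <- water_scf()
  solve_ci(w$so, "CID", n_frozen = 1, tol = 1e-12)
})

water_cid_aat <- function() memo("water_cid_aat", function() {
  aat_analytic(fixture_geometry("water_c2v"), "6-31G", "CID",
               frozen_core = TRUE, normalization = "full", conv = 1e-11)
})

# random antisymmetrized doubles tensor for oracle tests
random_c2 <- function(no, nv) {
  c2 <- array(rnorm(no^2 * nv^2), c(no, no, nv, nv))
  c2 <- c2 - aperm(c2, c(2, 1, 3, 4))
  c2 - aperm(c2, c(1, 2, 4, 3))
}

# random antisymmetrized two-electron tensor, Hermitian or anti-Hermitian
random_g <- function(nso, herm = TRUE) {
  g <- array(rnorm(nso^4), rep(nso, 4))
  g <- g - aperm(g, c(2, 1, 3, 4))
  g <- g - aperm(g, c(1, 2, 4, 3))
  if (herm) g + aperm(g, c(3, 4, 1, 2)) else g - aperm(g, c(3, 4, 1, 2))
}
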
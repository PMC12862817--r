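test_that("XYZ I/O round-trips and validates its input", {
  mol <- fixture_geometry("water_c2v")
  f <- tempfile(fileext = ".xyz")
  write_xyz(mol, f)
  back <- load_xyz(f)
  expect_lt(max(abs(back$coords - mol$coords)), 1e-12)
  expect_identical(back$symbols, mol$symbols)
  expect_equal(back$charges, c(8, 1, 1))

  # unit handling: 1 angstrom -> bohr
  writeLines(c("1", "", "H 1.0 0.0 0.0"), f)
  m1 <- load_xyz(f, "angstrom")
  expect_equal(max(abs(m1$coords)), 1.8897261258, tolerance = 1e-9)

  writeLines(c("4", "", "O 0 0 0", "H 1 0 0", "H 0 1 0"), f)
  expect_error(load_xyz(f), "count line says 4")
  writeLines(c("1", "", "Xx 0 0 0"), f)
  expect_error(load_xyz(f), "unknown element")
  writeLines(c("1", "", "H a 0 0"), f)
  expect_error(load_xyz(f), "non-numeric")
})

test_that("center-of-mass shift is exact and idempotent", {
  he <- molecule("He", matrix(c(1, 2, 3), 1, 3))
  expect_equal(max(abs(shift_to_com(he)$coords)), 0)
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 1), c(0, 0, 3)))
  expect_equal(shift_to_com(h2)$coords[, 3], c(-1, 1))
  w <- fixture_geometry("water_c2v")
  expect_lt(max(abs(colSums(w$coords * w$masses))), 1e-12)
  w2 <- shift_to_com(w)
  expect_lt(max(abs(w2$coords - w$coords)), 1e-14)
})

test_that("fixture geometries obey their documented conventions", {
  w <- fixture_geometry("water_c2v")
  expect_lt(max(abs(w$coords[, 1])), 1e-14)          # all atoms in yz plane
  expect_equal(w$coords[2, 2], -w$coords[3, 2])      # C2(z) relates hydrogens
  p <- fixture_geometry("hooh_P")
  m <- fixture_geometry("hooh_M")
  expect_equal(dihedral_angle(p, 1, 3, 4, 2), 115, tolerance = 1e-9)
  expect_equal(dihedral_angle(m, 1, 3, 4, 2), -115, tolerance = 1e-9)
  expect_equal(max(abs(fixture_geometry("he")$coords)), 0)
  expect_error(fixture_geometry("nope"), "unknown fixture")
})
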
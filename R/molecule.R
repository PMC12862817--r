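# Molecular geometry model: XYZ I/O, masses, center-of-mass gauge origin and
# the documented validation fixtures.

#' Construct a molecule
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in bohr.
#' @param net_charge integer net charge.
#' @param multiplicity spin multiplicity; only closed-shell singlets are
#'   supported by the electronic-structure layer.
#' @return An object of class `molecule` with fields `symbols`, `charges`
#'   (nuclear charges), `coords` (bohr), `masses` (amu, most abundant
#'   isotope), `net_charge`, `multiplicity`.
#' @export
molecule <- function(symbols, coords, net_charge = 0L, multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) != nrow(coords))
    stop("number of symbols (", length(symbols), ") != number of coordinate triples (",
         nrow(coords), ")")
  Z <- element_number(symbols)
  m <- element_mass(symbols)
  structure(list(symbols = as.character(symbols), charges = as.numeric(Z),
                 coords = coords, masses = m,
                 net_charge = as.integer(net_charge),
                 multiplicity = as.integer(multiplicity)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, charge %d, multiplicity %d (coordinates in bohr)\n",
              nrow(x$coords), x$net_charge, x$multiplicity))
  for (i in seq_along(x$symbols))
    cat(sprintf("  %-2s %14.8f %14.8f %14.8f\n", x$symbols[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  invisible(x)
}

n_electrons <- function(mol) sum(mol$charges) - mol$net_charge

nuclear_repulsion <- function(mol) {
  n <- nrow(mol$coords)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    e <- e + mol$charges[i] * mol$charges[j] / r
  }
  e
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom.  Element symbols are case-insensitive.
#'
#' @param path file path.
#' @param unit unit of the coordinates in the file, `"angstrom"` (the XYZ
#'   convention, default) or `"bohr"`.
#' @return A [molecule()] with coordinates stored in bohr.
#' @export
load_xyz <- function(path, unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) < 2) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("XYZ parse error: count line says ", n, " atoms but only ",
         length(body), " atom lines found")
  syms <- character(n); xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(toks) < 4)
      stop("XYZ parse error at line ", i + 2, ": expected 'symbol x y z'")
    v <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(v))
      stop("XYZ parse error at line ", i + 2, ": non-numeric coordinate")
    syms[i] <- toks[1]; xyz[i, ] <- v
  }
  if (unit == "angstrom") xyz <- xyz * vcd_constants$bohr_per_angstrom
  molecule(syms, xyz)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @param unit output unit, `"angstrom"` (default) or `"bohr"`.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, unit = c("angstrom", "bohr"), comment = "") {
  unit <- match.arg(unit)
  xyz <- mol$coords
  if (unit == "angstrom") xyz <- xyz / vcd_constants$bohr_per_angstrom
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(xyz)), comment), con)
  for (i in seq_along(mol$symbols))
    writeLines(sprintf("%-2s %20.14f %20.14f %20.14f", mol$symbols[i],
                       xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
  invisible(path)
}

#' Shift a molecule to its center of mass
#'
#' The center of mass is the gauge origin for all magnetic-property
#' integrals, so geometries are shifted before any calculation.
#'
#' @param mol a [molecule()].
#' @return The molecule translated so that `sum(m_lambda * R_lambda) = 0`.
#' @export
shift_to_com <- function(mol) {
  com <- colSums(mol$coords * mol$masses) / sum(mol$masses)
  mol$coords <- sweep(mol$coords, 2, com)
  mol
}

is_at_com <- function(mol, tol = 1e-10) {
  all(abs(colSums(mol$coords * mol$masses)) < tol * sum(mol$masses))
}

#' Built-in validation geometries
#'
#' Deterministic, documented geometries used throughout the validation suite:
#' \describe{
#'   \item{he}{a single helium atom.}
#'   \item{h2}{H2 at r = 0.74 angstrom along z.}
#'   \item{h2_dimer}{two H2 units in a skewed (chiral) arrangement separated
#'     by 3 angstrom, a minimal system with no spatial symmetry.}
#'   \item{water_c2v}{C2v water, r(OH) = 0.96 angstrom, angle 104.5 degrees,
#'     oriented with the C2 axis along z and all atoms in the yz plane.}
#'   \item{hooh_P}{(P)-hydrogen peroxide, r(OH) = 0.97 angstrom,
#'     r(OO) = 1.45 angstrom, angle(OOH) = 100 degrees, dihedral +115
#'     degrees (the sign that yields P axial chirality), oriented with the
#'     C2 axis along z.}
#'   \item{hooh_M}{the mirror image of `hooh_P` (dihedral -115 degrees).}
#' }
#' All fixtures are returned shifted to their center of mass.
#'
#' @param name one of `"he"`, `"h2"`, `"h2_dimer"`, `"water_c2v"`,
#'   `"hooh_P"`, `"hooh_M"`.
#' @return A [molecule()] at its center of mass.
#' @export
fixture_geometry <- function(name) {
  ang <- vcd_constants$bohr_per_angstrom
  mol <- switch(name,
    he = molecule("He", matrix(c(0, 0, 0), 1, 3)),
    h2 = molecule(c("H", "H"),
                  rbind(c(0, 0, -0.37), c(0, 0, 0.37)) * ang),
    h2_dimer = {
      # Two H2 units, the second displaced along x and twisted: no symmetry.
      a <- rbind(c(0, 0, -0.37), c(0, 0, 0.37))
      b <- rbind(c(3.0, -0.26, 0.20), c(3.0, 0.26, -0.54)) +
        matrix(c(0, 0.1, 0.17), 2, 3, byrow = TRUE)
      molecule(rep("H", 4), rbind(a, b) * ang)
    },
    water_c2v = {
      r <- 0.96; theta <- 104.5 * pi / 180
      y <- r * sin(theta / 2); z <- r * cos(theta / 2)
      molecule(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(0, y, z), c(0, -y, z)) * ang)
    },
    hooh_P = hooh_geometry(+115),
    hooh_M = hooh_geometry(-115),
    stop("unknown fixture name: '", name, "'")
  )
  shift_to_com(mol)
}

# (P)/(M)-H2O2 with the C2 axis along z: O-O bond along x centered at the
# origin; the two OH hydrogens are related by C2(z).
hooh_geometry <- function(dihedral_deg) {
  ang <- vcd_constants$bohr_per_angstrom
  r_oo <- 1.45; r_oh <- 0.97; a_ooh <- 100 * pi / 180
  phi <- dihedral_deg * pi / 180
  o1 <- c(-r_oo / 2, 0, 0)
  o2 <- c(+r_oo / 2, 0, 0)
  # H on O1: the O3->H direction makes angle(O4-O3-H) = 100 deg with the
  # O3->O4 (+x) direction; its perpendicular component sits at azimuth
  # alpha about the O-O axis, chosen so that together with the C2(z) image
  # below the signed H1-O3-O4-H2 dihedral equals phi.
  alpha <- -sign(phi) * (pi - abs(phi)) / 2
  perp1 <- c(0, cos(alpha), sin(alpha))
  h1 <- o1 + r_oh * (-cos(a_ooh) * c(1, 0, 0) + sin(a_ooh) * perp1)
  # C2(z): (x, y, z) -> (-x, -y, z)
  h2 <- c(-h1[1], -h1[2], h1[3])
  molecule(c("H", "H", "O", "O"), rbind(h1, h2, o1, o2) * ang)
}

#' Signed dihedral angle between four atoms
#'
#' @param mol a [molecule()].
#' @param i,j,k,l 1-based atom indices defining the i-j-k-l dihedral.
#' @return Signed dihedral in degrees (IUPAC sign convention).
#' @export
dihedral_angle <- function(mol, i, j, k, l) {
  p <- mol$coords
  b1 <- p[j, ] - p[i, ]; b2 <- p[k, ] - p[j, ]; b3 <- p[l, ] - p[k, ]
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
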
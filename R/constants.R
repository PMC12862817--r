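# Physical constants and unit conversions (CODATA 2018).  All electronic
# structure is done in Hartree atomic units; conversions are applied only at
# the I/O boundary (geometries in angstrom, spectra in cm^-1, rotatory
# strengths in 10^-44 esu^2 cm^2).

#' Physical constants used throughout the package
#'
#' A named list of the unit conversions and physical constants the package
#' relies on.  Everything internal is in Hartree atomic units; these factors
#' are applied only when reading input or formatting output.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{bohr_per_angstrom}{1 angstrom in bohr (1.8897261258...)}
#'   \item{fine_structure_c}{speed of light in atomic units (inverse fine
#'     structure constant), 137.035999}
#'   \item{amu_to_me}{1 unified atomic mass unit in electron masses}
#'   \item{hartree_to_wavenumber}{1 hartree in cm^-1}
#'   \item{debye_per_au}{1 atomic unit of electric dipole in debye}
#'   \item{rotatory_au_to_cgs44}{1 atomic unit of rotatory strength
#'     (electric dipole a.u. times magnetic dipole a.u.) in units of
#'     10^-44 esu^2 cm^2}
#' }
#' @export
vcd_constants <- list(
  bohr_per_angstrom     = 1.8897261258369282,
  fine_structure_c      = 137.035999084,
  amu_to_me             = 1822.888486209,
  hartree_to_wavenumber = 219474.6313632,
  debye_per_au          = 2.541746473,
  # e*a0 = 2.541746473e-18 esu cm ; e*hbar/m_e = 2 mu_B = 1.85480201e-20 erg/G
  # product in 10^-44 esu^2 cm^2: 2.541746473e-18 * 1.85480201e-20 / 1e-44
  rotatory_au_to_cgs44  = 2.541746473 * 1.85480201 * 1e6
)

# Atomic masses of the most abundant isotope (amu).  A single embedded table
# keeps center-of-mass origins and normal modes bit-reproducible.
.element_data <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z      = 1:18,
  mass   = c(1.00782503207, 4.00260325415, 7.016004548, 9.012182201,
             11.009305406, 12.0, 14.0030740048, 15.99491461956,
             18.998403224, 19.99244017542, 22.98976928087, 23.985041699,
             26.981538627, 27.976926532, 30.973761629, 31.972070999,
             34.968852682, 39.962383123),
  stringsAsFactors = FALSE
)

element_number <- function(symbol) {
  idx <- match(toupper(symbol), toupper(.element_data$symbol))
  if (anyNA(idx)) {
    bad <- symbol[is.na(idx)]
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .element_data$Z[idx]
}

element_symbol <- function(Z) {
  idx <- match(Z, .element_data$Z)
  if (anyNA(idx)) stop("unsupported atomic number(s): ", paste(Z[is.na(idx)], collapse = ", "))
  .element_data$symbol[idx]
}

element_mass <- function(symbol) {
  .element_data$mass[match(toupper(symbol), toupper(.element_data$symbol))]
}
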
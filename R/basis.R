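# Basis-set library: Gaussian-format (.gbs) parsing and expansion of shells
# into normalized Cartesian contracted Gaussian basis functions.

double_factorial <- function(n) {
  # (-1)!! = 1 by convention
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

basis_file_for <- function(name) {
  file <- system.file("extdata", "basis",
                      paste0(tolower(gsub("\\*", "s", name)), ".gbs"),
                      package = "vcdci")
  if (!nzchar(file))
    stop("basis set '", name, "' not found in the package basis library")
  file
}

# Parse a Gaussian94-format basis file into a per-element list of shells.
parse_gbs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*!", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    elem <- hdr[1]; i <- i + 1
    shells <- list()
    while (i <= length(lines) && lines[i] != "****") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1]); nprim <- as.integer(sh[2]); i <- i + 1
      rows <- do.call(rbind, lapply(lines[i:(i + nprim - 1)], function(l) {
        as.numeric(gsub("D", "E", strsplit(l, "\\s+")[[1]], ignore.case = TRUE))
      }))
      i <- i + nprim
      shells[[length(shells) + 1]] <- list(type = type, expo = rows[, 1],
                                           coef = rows[, -1, drop = FALSE])
    }
    out[[elem]] <- shells
  }
  out
}

.shell_l <- c(S = 0L, P = 1L, D = 2L, F = 3L)

# Cartesian component exponents for angular momentum l, fixed ordering.
cart_components <- function(l) {
  comps <- list()
  for (lx in seq(l, 0)) for (ly in seq(l - lx, 0)) {
    comps[[length(comps) + 1]] <- c(lx, ly, l - lx - ly)
  }
  do.call(rbind, comps)
}

primitive_norm <- function(a, lx, ly, lz) {
  l <- lx + ly + lz
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) /
    sqrt(double_factorial(2 * lx - 1) * double_factorial(2 * ly - 1) *
         double_factorial(2 * lz - 1))
}

#' Build a basis set for a molecule
#'
#' Expands the named basis set over the atoms of `mol` into a flat list of
#' normalized Cartesian contracted Gaussian basis functions (6d convention).
#'
#' @param mol a [molecule()].
#' @param basis basis-set name (case-insensitive), e.g. `"6-31G"` or
#'   `"aug-cc-pVDZ"`, resolved from the package basis library.
#' @return An object of class `basis_set`: list with `nbf` and parallel
#'   per-function vectors/matrices `l` (nbf x 3 Cartesian exponents), `atom`
#'   (1-based atom index), `center` (nbf x 3, bohr), and ragged `expo`,
#'   `coef` lists of primitive exponents and normalized coefficients.
#' @export
build_basis <- function(mol, basis) {
  lib <- parse_gbs(basis_file_for(basis))
  l_list <- list(); atom <- integer(); center <- list()
  expo <- list(); coef <- list()
  for (ia in seq_along(mol$symbols)) {
    sym <- mol$symbols[ia]
    key <- names(lib)[match(toupper(sym), toupper(names(lib)))]
    if (is.na(key))
      stop("basis set has no entry for element '", sym, "'")
    for (sh in lib[[key]]) {
      types <- if (sh$type == "SP") c("S", "P") else sh$type
      for (tix in seq_along(types)) {
        l <- .shell_l[[types[tix]]]
        comps <- cart_components(l)
        cvec <- sh$coef[, min(tix, ncol(sh$coef))]
        if (sh$type == "SP") cvec <- sh$coef[, tix]
        for (ic in seq_len(nrow(comps))) {
          lx <- comps[ic, 1]; ly <- comps[ic, 2]; lz <- comps[ic, 3]
          cn <- cvec * primitive_norm(sh$expo, lx, ly, lz)
          # contraction normalization from the closed-form self-overlap
          ang <- double_factorial(2 * lx - 1) * double_factorial(2 * ly - 1) *
            double_factorial(2 * lz - 1)
          ssum <- 0
          for (i in seq_along(sh$expo)) for (j in seq_along(sh$expo)) {
            p <- sh$expo[i] + sh$expo[j]
            ssum <- ssum + cn[i] * cn[j] * ang / (2 * p)^l * (pi / p)^1.5
          }
          cn <- cn / sqrt(ssum)
          l_list[[length(l_list) + 1]] <- c(lx, ly, lz)
          atom <- c(atom, ia)
          center[[length(center) + 1]] <- mol$coords[ia, ]
          expo[[length(expo) + 1]] <- sh$expo
          coef[[length(coef) + 1]] <- cn
        }
      }
    }
  }
  structure(list(nbf = length(atom), l = do.call(rbind, l_list), atom = atom,
                 center = do.call(rbind, center), expo = expo, coef = coef,
                 name = basis),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %s: %d Cartesian basis functions\n", x$name, x$nbf))
  invisible(x)
}
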
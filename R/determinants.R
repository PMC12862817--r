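# Determinant space enumeration and addressing for CID/CISD in the
# spin-orbital basis, plus a slow brute-force determinant algebra used as an
# internal oracle for the contraction-based production code.

#' Enumerate the CI determinant space
#'
#' Singles and doubles are labeled with the second-quantized convention
#' `Phi_i^a = a_a+ a_i Phi0`, `Phi_ij^ab = a_a+ a_b+ a_j a_i Phi0` (i<j,
#' a<b canonical storage).  Each excited determinant is also stored as a
#' sorted occupation list together with the phase connecting the two
#' conventions, so dense (sorted-determinant) and tensor (excitation
#' labeled) representations can be interconverted exactly.
#'
#' @param n_occ_so number of occupied spin orbitals (= electrons).
#' @param nso total spin orbitals.
#' @param n_frozen_so frozen-core spin orbitals (excluded from excitations).
#' @param level `"CISD"` or `"CID"` (no singles).
#' @return Object of class `det_space`: `dets` (ndet x nel matrix, sorted,
#'   reference first), `phase`, `labels` (list with type/i/j/a/b),
#'   `occ_active`, `virt`, index maps `s_index` (i,a -> det row) and
#'   `d_index` (i<j,a<b -> det row).
#' @export
det_space <- function(n_occ_so, nso, n_frozen_so = 0, level = c("CISD", "CID")) {
  level <- match.arg(level)
  nel <- n_occ_so
  occ <- seq_len(n_occ_so)
  occ_active <- setdiff(occ, seq_len(n_frozen_so))
  virt <- setdiff(seq_len(nso), occ)
  dets <- list(occ)
  phase <- 1
  labels <- list(list(type = "ref"))
  s_index <- NULL
  if (level == "CISD") {
    s_index <- matrix(NA_integer_, length(occ_active), length(virt))
    for (ii in seq_along(occ_active)) for (aa in seq_along(virt)) {
      res <- apply_excitation(occ, occ_active[ii], virt[aa])
      dets[[length(dets) + 1]] <- res$det
      phase <- c(phase, res$phase)
      labels[[length(labels) + 1]] <- list(type = "s", i = occ_active[ii], a = virt[aa])
      s_index[ii, aa] <- length(dets)
    }
  }
  no <- length(occ_active); nv <- length(virt)
  d_index <- array(NA_integer_, c(no, no, nv, nv))
  for (ii in seq_len(no - 1)) for (jj in seq(ii + 1, no))
    for (aa in seq_len(nv - 1)) for (bb in seq(aa + 1, nv)) {
      i <- occ_active[ii]; j <- occ_active[jj]
      a <- virt[aa]; b <- virt[bb]
      # Phi_ij^ab = a_a+ a_b+ a_j a_i Phi0
      r1 <- apply_annihilation(occ, i)
      r2 <- apply_annihilation(r1$det, j)
      r3 <- apply_creation(r2$det, b)
      r4 <- apply_creation(r3$det, a)
      dets[[length(dets) + 1]] <- r4$det
      phase <- c(phase, r1$phase * r2$phase * r3$phase * r4$phase)
      labels[[length(labels) + 1]] <- list(type = "d", i = i, j = j, a = a, b = b)
      d_index[ii, jj, aa, bb] <- length(dets)
    }
  structure(list(dets = do.call(rbind, dets), phase = phase, labels = labels,
                 occ = occ, occ_active = occ_active, virt = virt,
                 n_frozen_so = n_frozen_so, nso = nso, level = level,
                 s_index = s_index, d_index = d_index),
            class = "det_space")
}

#' @export
print.det_space <- function(x, ...) {
  cat(sprintf("<det_space> %s, %d determinants (%d electrons, %d spin orbitals, %d frozen)\n",
              x$level, nrow(x$dets), length(x$occ), x$nso, x$n_frozen_so))
  invisible(x)
}

apply_annihilation <- function(det, p) {
  pos <- match(p, det)
  if (is.na(pos)) return(list(det = NULL, phase = 0))
  list(det = det[-pos], phase = (-1)^(pos - 1))
}

apply_creation <- function(det, p) {
  if (p %in% det) return(list(det = NULL, phase = 0))
  nbefore <- sum(det < p)
  list(det = sort(c(det, p)), phase = (-1)^nbefore)
}

apply_excitation <- function(occ, i, a) {
  r1 <- apply_annihilation(occ, i)
  r2 <- apply_creation(r1$det, a)
  list(det = r2$det, phase = r1$phase * r2$phase)
}

# ---- packed tensor <-> sorted-determinant vector conversions ---------------

# Tensor representation: c0 scalar, c1 [no x nv] (0 rows for CID), c2 full
# antisymmetrized [no x no x nv x nv] over active occ / virt.
tensor_to_detvec <- function(space, c0, c1, c2) {
  no <- length(space$occ_active); nv <- length(space$virt)
  v <- numeric(nrow(space$dets))
  v[1] <- c0
  if (!is.null(space$s_index) && !is.null(c1))
    v[space$s_index] <- c1
  for (ii in seq_len(no - 1)) for (jj in seq(ii + 1, no))
    for (aa in seq_len(nv - 1)) for (bb in seq(aa + 1, nv)) {
      k <- space$d_index[ii, jj, aa, bb]
      v[k] <- c2[ii, jj, aa, bb]
    }
  v * space$phase
}

detvec_to_tensor <- function(space, v) {
  no <- length(space$occ_active); nv <- length(space$virt)
  v <- v * space$phase  # phases are +/-1
  c0 <- v[1]
  c1 <- if (!is.null(space$s_index)) matrix(v[space$s_index], no, nv) else
    matrix(0, no, nv)
  c2 <- array(0, c(no, no, nv, nv))
  for (ii in seq_len(no - 1)) for (jj in seq(ii + 1, no))
    for (aa in seq_len(nv - 1)) for (bb in seq(aa + 1, nv)) {
      x <- v[space$d_index[ii, jj, aa, bb]]
      c2[ii, jj, aa, bb] <- x; c2[jj, ii, aa, bb] <- -x
      c2[ii, jj, bb, aa] <- -x; c2[jj, ii, bb, aa] <- x
    }
  list(c0 = c0, c1 = c1, c2 = c2)
}

# ---- brute-force determinant algebra (internal oracle) ---------------------

# Apply a one-body operator T = sum_{qp} t[q, p] a_q+ a_p to a wavefunction
# given as a named list det-string -> amplitude.  Returns the same
# representation (possibly over a larger determinant set).
det_key <- function(det) paste(det, collapse = ",")

brute_obody_apply <- function(wf, tmat) {
  out <- new.env(parent = emptyenv())
  nso <- nrow(tmat)
  for (key in names(wf)) {
    amp <- wf[[key]]
    det <- as.integer(strsplit(key, ",")[[1]])
    for (p in det) {
      r1 <- apply_annihilation(det, p)
      for (q in seq_len(nso)) {
        t <- tmat[q, p]
        if (t == 0) next
        r2 <- apply_creation(r1$det, q)
        if (r2$phase == 0) next
        k2 <- det_key(r2$det)
        prev <- if (!is.null(out[[k2]])) out[[k2]] else 0
        out[[k2]] <- prev + amp * r1$phase * r2$phase * t
      }
    }
  }
  as.list(out)
}

brute_wf_from_tensor <- function(space, c0, c1, c2) {
  v <- tensor_to_detvec(space, c0, c1, c2)
  wf <- list()
  for (k in seq_along(v)) {
    if (v[k] != 0) wf[[det_key(space$dets[k, ])]] <- v[k]
  }
  wf
}

brute_dot <- function(wfL, wfR) {
  s <- 0
  for (key in names(wfL)) {
    if (!is.null(wfR[[key]])) s <- s + wfL[[key]] * wfR[[key]]
  }
  s
}
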
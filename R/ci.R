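# CID/CISD ground states in the spin-orbital determinant basis under
# intermediate normalization, plus MP2 first-order amplitudes.  Small spaces
# use a dense Slater-Condon Hamiltonian; larger spaces use contraction-based
# sigma builds inside a Davidson solver.  The two routes are checked against
# each other in the test suite.

# Fold frozen-core orbitals into an effective one-electron operator and a
# scalar.  `ord` maps active-space index -> absolute spin-orbital index.
ci_hamiltonian <- function(h, g, n_occ_so, n_frozen_so) {
  nso <- nrow(h)
  core <- seq_len(n_frozen_so)
  act <- setdiff(seq_len(nso), core)
  Ecore <- 0
  if (n_frozen_so > 0) {
    Ecore <- sum(diag(h)[core])
    for (m in core) for (n in core) Ecore <- Ecore + 0.5 * g[m, n, m, n]
    hcv <- h[act, act]
    for (m in core) hcv <- hcv + g[act, m, act, m]
    t <- hcv
  } else {
    t <- h
  }
  no <- n_occ_so - n_frozen_so
  nv <- nso - n_occ_so
  list(Ecore = Ecore, t = t, g = g[act, act, act, act, drop = FALSE],
       no = no, nv = nv, ord = act, n_occ_so = n_occ_so,
       n_frozen_so = n_frozen_so, nso = nso)
}

ci_fock <- function(ham) {
  no <- ham$no; nact <- ham$no + ham$nv
  F <- ham$t
  for (k in seq_len(no)) F <- F + ham$g[, k, , k]
  F
}

ci_e0 <- function(ham) {
  no <- ham$no
  occ <- seq_len(no)
  e <- ham$Ecore + sum(diag(ham$t)[occ])
  for (i in occ) for (j in occ) e <- e + 0.5 * ham$g[i, j, i, j]
  e
}

# ---- packed vector layout: c(c0, c1, c2[i<j,a<b]) --------------------------

ci_packing <- function(no, nv, level) {
  ns <- if (level == "CISD") no * nv else 0
  dp <- list()
  if (no >= 2 && nv >= 2) {
    ij <- which(upper.tri(matrix(0, no, no)), arr.ind = TRUE)
    ab <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
    dp <- list(ij = ij, ab = ab)
  }
  nd <- if (length(dp)) nrow(dp$ij) * nrow(dp$ab) else 0
  list(no = no, nv = nv, level = level, ns = ns, nd = nd, len = 1 + ns + nd,
       dp = dp)
}

pack_ci <- function(pk, c0, c1, c2) {
  cplx <- is.complex(c0) || is.complex(c1) || is.complex(c2)
  v <- vector(if (cplx) "complex" else "numeric", pk$len)
  v[1] <- c0
  if (pk$ns > 0) v[1 + seq_len(pk$ns)] <- as.vector(c1)
  if (pk$nd > 0) {
    ij <- pk$dp$ij; ab <- pk$dp$ab
    # c2 block in order: for each (a<b) pair, all (i<j) pairs
    m <- matrix(c2[cbind(rep(ij[, 1], nrow(ab)), rep(ij[, 2], nrow(ab)),
                         rep(ab[, 1], each = nrow(ij)), rep(ab[, 2], each = nrow(ij)))],
                nrow(ij), nrow(ab))
    v[1 + pk$ns + seq_len(pk$nd)] <- as.vector(m)
  }
  v
}

unpack_ci <- function(pk, v) {
  zero <- if (is.complex(v)) 0 + 0i else 0
  c0 <- v[1]
  c1 <- matrix(zero, pk$no, pk$nv)
  if (pk$ns > 0) c1 <- matrix(v[1 + seq_len(pk$ns)], pk$no, pk$nv)
  c2 <- array(zero, c(pk$no, pk$no, pk$nv, pk$nv))
  if (pk$nd > 0) {
    ij <- pk$dp$ij; ab <- pk$dp$ab
    x <- v[1 + pk$ns + seq_len(pk$nd)]
    i1 <- rep(ij[, 1], nrow(ab)); i2 <- rep(ij[, 2], nrow(ab))
    a1 <- rep(ab[, 1], each = nrow(ij)); a2 <- rep(ab[, 2], each = nrow(ij))
    c2[cbind(i1, i2, a1, a2)] <- x
    c2[cbind(i2, i1, a1, a2)] <- -x
    c2[cbind(i1, i2, a2, a1)] <- -x
    c2[cbind(i2, i1, a2, a1)] <- x
  }
  list(c0 = c0, c1 = c1, c2 = c2)
}

# ---- contraction sigma -----------------------------------------------------

# Antisymmetrizers over the two occupied / two virtual slots of [i,j,a,b]
anti_ij <- function(x) x - aperm(x, c(2, 1, 3, 4))
anti_ab <- function(x) x - aperm(x, c(1, 2, 4, 3))
anti_ijab <- function(x) anti_ab(anti_ij(x))

# sigma = H * c on the CISD space for a generic one-/two-electron operator
# (real or complex; h need not be symmetric -- used for derivative
# Hamiltonians).  Index blocks: occupied 1..no and virtual no+1..no+nv of
# the active ordering.  F and E0 must be precomputed from `ham` with
# ci_fock()/ci_e0().
sigma_cisd <- function(ham, F, E0, c0, c1, c2, level) {
  no <- ham$no; nv <- ham$nv
  o <- seq_len(no); v <- no + seq_len(nv)
  g <- ham$g
  Fov <- F[o, v, drop = FALSE]; Fvo <- F[v, o, drop = FALSE]
  Fvv <- F[v, v, drop = FALSE]; Foo <- F[o, o, drop = FALSE]
  goovv <- g[o, o, v, v, drop = FALSE]

  s0 <- E0 * c0 + 0.25 * sum(goovv * c2)
  if (level == "CISD") s0 <- s0 + sum(Fov * c1)

  # ---- doubles sigma
  s2 <- E0 * c2 + c0 * aperm(g[v, v, o, o, drop = FALSE], c(3, 4, 1, 2))
  # P(ab) sum_c c2[i,j,a,c] F[b,c]
  X <- array(matrix(c2, no * no * nv, nv) %*% t(Fvv), c(no, no, nv, nv))
  s2 <- s2 + anti_ab(X)
  # - P(ij) sum_k F[k,j] c2[i,k,a,b]
  Y <- aperm(array(matrix(aperm(c2, c(1, 3, 4, 2)), no * nv * nv, no) %*% Foo,
                   c(no, nv, nv, no)), c(1, 4, 2, 3))
  s2 <- s2 - anti_ij(Y)
  # + 1/2 sum_kl <kl||ij> c2[k,l,a,b]
  goooo <- matrix(g[o, o, o, o, drop = FALSE], no * no, no * no)
  s2 <- s2 + 0.5 * array(t(goooo) %*% matrix(c2, no * no, nv * nv),
                         c(no, no, nv, nv))
  # + 1/2 sum_cd <ab||cd> c2[i,j,c,d]
  gvvvv <- matrix(g[v, v, v, v, drop = FALSE], nv * nv, nv * nv)
  s2 <- s2 + 0.5 * array(matrix(c2, no * no, nv * nv) %*% t(gvvvv),
                         c(no, no, nv, nv))
  # + P(ij)P(ab) sum_kc <kb||cj> c2[i,k,a,c]
  gg <- aperm(g[o, v, v, o, drop = FALSE], c(1, 3, 2, 4))   # [(k,c),(b,j)]
  cc <- matrix(aperm(c2, c(1, 3, 2, 4)), no * nv, no * nv)  # [(i,a),(k,c)]
  R <- aperm(array(cc %*% matrix(gg, no * nv, nv * no), c(no, nv, nv, no)),
             c(1, 4, 2, 3))
  s2 <- s2 + anti_ijab(R)

  # ---- singles sigma and singles-doubles couplings
  s1 <- matrix(0, no, nv)
  if (level == "CISD") {
    s1 <- E0 * c1 + c0 * t(Fvo) + c1 %*% t(Fvv) - t(Foo) %*% c1
    # + sum_jb <aj||ib> c1[j,b]
    gvoov <- aperm(g[v, o, o, v, drop = FALSE], c(3, 1, 2, 4))  # [i,a,j,b]
    s1 <- s1 + matrix(matrix(gvoov, no * nv, no * nv) %*% as.vector(c1), no, nv)
    # + sum_jb F[j,b] c2[i,j,a,b]
    s1 <- s1 + matrix(matrix(aperm(c2, c(1, 3, 2, 4)), no * nv, no * nv) %*%
                        as.vector(Fov), no, nv)
    # + 1/2 sum_jbc <aj||bc> c2[i,j,b,c]
    gvovv <- aperm(g[v, o, v, v, drop = FALSE], c(2, 3, 4, 1))  # [(j,b,c),a]
    s1 <- s1 + 0.5 * matrix(c2, no, no * nv * nv) %*%
      matrix(gvovv, no * nv * nv, nv)
    # - 1/2 sum_jkb <jk||ib> c2[j,k,a,b]
    gooov <- aperm(g[o, o, o, v, drop = FALSE], c(3, 1, 2, 4))  # [i,(j,k,b)]
    s1 <- s1 - 0.5 * matrix(gooov, no, no * no * nv) %*%
      matrix(aperm(c2, c(1, 2, 4, 3)), no * no * nv, nv)
    # doubles sigma couplings to singles:
    # + P(ij) sum_c <ab||cj> c1[i,c]
    gvvvo <- aperm(g[v, v, v, o, drop = FALSE], c(3, 1, 2, 4))  # [c,(a,b,j)]
    Xs <- aperm(array(c1 %*% matrix(gvvvo, nv, nv * nv * no),
                      c(no, nv, nv, no)), c(1, 4, 2, 3))
    s2 <- s2 + anti_ij(Xs)
    # - P(ab) sum_k <kb||ij> c1[k,a]
    govoo <- matrix(g[o, v, o, o, drop = FALSE], no, nv * no * no)
    Ys <- aperm(array(t(c1) %*% govoo, c(nv, nv, no, no)), c(3, 4, 1, 2))
    s2 <- s2 - anti_ab(Ys)
    # + P(ij)P(ab) c1[i,a] F[b,j]
    W <- aperm(outer(c1, t(Fvo)), c(1, 3, 2, 4))
    s2 <- s2 + anti_ijab(W)
  }
  list(s0 = s0, s1 = s1, s2 = s2)
}

# packed-vector sigma closure for the iterative solvers
make_sigma <- function(ham, level, pk) {
  F <- ci_fock(ham); E0 <- ci_e0(ham)
  function(vec) {
    cv <- unpack_ci(pk, vec)
    s <- sigma_cisd(ham, F, E0, cv$c0, cv$c1, cv$c2, level)
    pack_ci(pk, s$s0, s$s1, s$s2)
  }
}

# ---- Davidson eigensolver --------------------------------------------------

# Lowest eigenpair of a (real symmetric or complex Hermitian) operator given
# as a matvec closure.  `dg` is the diagonal used for preconditioning.
davidson <- function(matvec, dg, v0, tol = 1e-10, maxiter = 300, maxsub = 30) {
  n <- length(v0)
  v0 <- v0 / sqrt(sum(Mod(v0)^2))
  B <- matrix(v0, n, 1)
  HB <- matrix(matvec(v0), n, 1)
  theta <- NA
  best <- list(resid = Inf); stall <- 0
  for (it in seq_len(maxiter)) {
    G <- Conj(t(B)) %*% HB
    G <- (G + Conj(t(G))) / 2
    es <- eigen(G, symmetric = TRUE)
    k <- which.min(es$values)
    theta <- es$values[k]
    y <- es$vectors[, k]
    x <- as.vector(B %*% y)
    Hx <- as.vector(HB %*% y)
    r <- Hx - theta * x
    rn <- sqrt(sum(Mod(r)^2)) / max(1, abs(theta))
    if (rn < best$resid) {
      best <- list(value = theta, vector = x, iters = it, resid = rn)
      stall <- 0
    } else stall <- stall + 1
    if (rn < tol) return(list(value = theta, vector = x, iters = it, resid = rn))
    if (stall >= 8) return(best)  # numerical floor for this operator
    if (ncol(B) >= maxsub) {  # restart with current best
      B <- matrix(x, n, 1)
      HB <- matrix(Hx, n, 1)
    }
    d <- dg - theta
    d[abs(d) < 1e-8] <- 1e-8 * sign(d[abs(d) < 1e-8] + 1e-300)
    t_new <- -r / d
    # orthogonalize twice against the subspace
    for (rep in 1:2) t_new <- t_new - B %*% (Conj(t(B)) %*% t_new)
    tn <- sqrt(sum(Mod(t_new)^2))
    if (tn < 1e-10 * sqrt(sum(Mod(r)^2)) || tn == 0) {
      # subspace cannot be extended further: residual is at the numerical
      # floor for this operator; accept the current pair
      return(list(value = theta, vector = x, iters = it, resid = rn))
    }
    t_new <- t_new / tn
    B <- cbind(B, as.vector(t_new))
    HB <- cbind(HB, matvec(as.vector(t_new)))
  }
  stop("Davidson failed to converge: relative residual ", format(rn),
       " after ", maxiter, " iterations")
}

# conjugate-gradient solve of A x = b with Jacobi preconditioner (A symmetric
# positive definite on the solve subspace)
cg_solve <- function(matvec, dg, b, tol = 1e-10, maxiter = 500) {
  cdot <- function(a, v) Re(sum(Conj(a) * v))
  x <- 0 * b
  r <- b
  dg_safe <- ifelse(abs(dg) < 1e-8, 1e-8, dg)
  z <- r / dg_safe
  p <- z
  rz <- cdot(r, z)
  bn <- sqrt(cdot(b, b))
  if (bn == 0) return(x)
  best <- x; best_rn <- bn
  for (it in seq_len(maxiter)) {
    Ap <- matvec(p)
    alpha <- rz / cdot(p, Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(cdot(r, r))
    if (rn < best_rn) { best <- x; best_rn <- rn }
    if (rn < tol * max(1, bn)) return(x)
    z <- r / dg_safe
    rz_new <- cdot(r, z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  best
}

# Rayleigh-quotient refinement of a converged eigenpair: a few projected-CG
# corrections drive the residual to the numerical floor, which matters when
# finite differences divide eigenvector errors by a 1e-6 step.
refine_eigenpair <- function(matvec, dg, x, nsweep = 2, cg_tol = 1e-6) {
  cdot <- function(a, v) Re(sum(Conj(a) * v))
  for (k in seq_len(nsweep)) {
    x <- x / sqrt(cdot(x, x))
    Hx <- matvec(x)
    theta <- cdot(x, Hx)
    r <- Hx - theta * x
    proj <- function(v) v - x * sum(Conj(x) * v)
    mv <- function(v) proj(matvec(proj(v)) - theta * proj(v))
    delta <- cg_solve(mv, dg - theta, -proj(r), tol = cg_tol, maxiter = 200)
    x <- x + proj(delta)
  }
  x <- x / sqrt(cdot(x, x))
  Hx <- matvec(x)
  theta <- cdot(x, Hx)
  list(vector = x, value = theta,
       resid = sqrt(cdot(Hx - theta * x, Hx - theta * x)))
}

# ---- ground-state solvers --------------------------------------------------

#' Solve the CID or CISD ground state
#'
#' Lowest eigenpair of the CI Hamiltonian in the singles+doubles (or doubles
#' only) excitation space, rescaled to intermediate normalization (the
#' reference coefficient is exactly 1).  Small determinant spaces use a
#' dense Slater-Condon Hamiltonian, larger ones contraction-based sigma
#' builds; both inside a Davidson solver.
#'
#' @param so a spin-orbital store from [to_spin_orbital()], or an
#'   `scf_result` (transformed internally).
#' @param level `"CISD"` or `"CID"`.
#' @param n_frozen number of frozen-core *spatial* orbitals.
#' @param tol residual threshold for the eigensolver.
#' @param guess optional packed start vector (warm restarts across displaced
#'   geometries).
#' @return Object of class `ci_wavefunction`: `c0` (= 1), `c1` (active-occ x
#'   virt, zero for CID), `c2` (full antisymmetrized rank-4), `E_elec`
#'   (electronic CI energy), `E_corr`, `E_tot`, `ham`, `pk`, `level`,
#'   `n_frozen`, `resid`.
#' @export
solve_ci <- function(so, level = c("CISD", "CID"), n_frozen = 0, tol = 1e-11,
                     guess = NULL) {
  level <- match.arg(level)
  if (inherits(so, "scf_result")) so <- to_spin_orbital(so)
  ham <- ci_hamiltonian(so$h, so$g, so$n_occ_so, 2 * n_frozen)
  # shift so the reference energy is ~0: keeps eigensolver rounding noise at
  # the correlation-energy scale instead of the total-energy scale
  eshift <- Re(ci_e0(ham))
  ham$Ecore <- ham$Ecore - eshift
  pk <- ci_packing(ham$no, ham$nv, level)
  sig <- make_sigma(ham, level, pk)
  dg <- ci_diag_approx(ham, pk)
  v0 <- if (!is.null(guess)) guess else {
    v <- numeric(pk$len); v[1] <- 1; v
  }
  sol <- davidson(sig, dg, v0, tol = tol)
  rf <- refine_eigenpair(sig, dg, sol$vector)
  sol$vector <- rf$vector; sol$value <- rf$value + eshift; sol$resid <- rf$resid
  if (abs(sol$vector[1]) < 0.5)
    warning("reference coefficient is small (|c0| = ",
            format(abs(sol$vector[1])), "); intermediate normalization is ",
            "ill-conditioned (multireference character)")
  vec <- sol$vector / sol$vector[1]
  cv <- unpack_ci(pk, vec)
  E_elec <- sol$value
  ham$Ecore <- ham$Ecore + eshift  # store the unshifted operator
  structure(list(level = level, c0 = 1, c1 = cv$c1, c2 = cv$c2,
                 E_elec = E_elec, E_corr = E_elec - (so$E_elec),
                 E_tot = E_elec + so$enuc, ham = ham, pk = pk,
                 n_frozen = n_frozen, resid = sol$resid, so = so,
                 vec_raw = sol$vector),
            class = "ci_wavefunction")
}

#' @export
print.ci_wavefunction <- function(x, ...) {
  cat(sprintf("<ci_wavefunction> %s: E = %.12f a.u. (E_corr = %.10f), frozen %d\n",
              x$level, x$E_tot, x$E_corr, x$n_frozen))
  invisible(x)
}

# approximate diagonal (orbital-energy differences) for preconditioning
ci_diag_approx <- function(ham, pk) {
  E0 <- Re(ci_e0(ham))
  F <- ci_fock(ham)
  no <- ham$no; nv <- ham$nv
  fo <- Re(diag(F))[seq_len(no)]; fv <- Re(diag(F))[no + seq_len(nv)]
  dg <- numeric(pk$len)
  dg[1] <- E0
  if (pk$ns > 0)
    dg[1 + seq_len(pk$ns)] <- E0 + as.vector(outer(-fo, fv, "+"))
  if (pk$nd > 0) {
    ij <- pk$dp$ij; ab <- pk$dp$ab
    docc <- -(fo[ij[, 1]] + fo[ij[, 2]])
    dvirt <- fv[ab[, 1]] + fv[ab[, 2]]
    dg[1 + pk$ns + seq_len(pk$nd)] <- E0 + as.vector(outer(docc, dvirt, "+"))
  }
  dg
}

#' MP2 first-order doubles amplitudes
#'
#' Canonical first-order amplitudes `c_ij^ab = <ij||ab> / (e_i + e_j - e_a -
#' e_b)` and the MP2 correlation energy, packaged like a CI wavefunction so
#' the response and AAT machinery can consume them unchanged.
#'
#' @inheritParams solve_ci
#' @return A `ci_wavefunction` with `level = "MP2"`.
#' @export
mp2_coefficients <- function(so, n_frozen = 0) {
  if (inherits(so, "scf_result")) so <- to_spin_orbital(so)
  ham <- ci_hamiltonian(so$h, so$g, so$n_occ_so, 2 * n_frozen)
  no <- ham$no; nv <- ham$nv
  o <- seq_len(no); v <- no + seq_len(nv)
  eps <- Re(diag(ci_fock(ham)))
  den <- array(0, c(no, no, nv, nv))
  den <- outer(outer(eps[o], eps[o], "+"), outer(eps[v], eps[v], "+"), "-")
  if (any(abs(den) < 1e-8))
    stop("vanishing MP2 denominator (degenerate occupied/virtual gap)")
  goovv <- ham$g[o, o, v, v, drop = FALSE]
  c2 <- goovv / den
  E_corr <- 0.25 * sum(goovv * c2)
  pk <- ci_packing(no, nv, "CID")
  structure(list(level = "MP2", c0 = 1, c1 = matrix(0, no, nv), c2 = c2,
                 E_elec = so$E_elec + E_corr, E_corr = E_corr,
                 E_tot = so$E_elec + E_corr + so$enuc, ham = ham, pk = pk,
                 n_frozen = n_frozen, resid = 0, so = so),
            class = "ci_wavefunction")
}
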
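---
title: "Analytic atomic axial tensors from CI wavefunctions: models, conventions, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic atomic axial tensors from CI wavefunctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The quantity being computed

Vibrational circular dichroism (VCD) — the differential absorption of left-
and right-circularly polarized infrared light — is governed, mode by mode, by
the rotatory strength, the imaginary part of the product of the electric and
magnetic dipole transition moments of a vibrational transition.  Within the
Born–Oppenheimer approximation the magnetic transition moment of a
vibrational fundamental vanishes unless the ground-state wavefunction is
perturbed to first order in both nuclear displacement and external magnetic
field.  The central electronic quantity is the atomic axial tensor (AAT),

$$ I^{\lambda}_{\alpha\beta}
 = \Big\langle \tfrac{\partial \Psi_G}{\partial R_{\lambda\alpha}}
 \Big|\, \tfrac{\partial \Psi_G}{\partial H_\beta} \Big\rangle , $$

the overlap of the nuclear-displacement derivative of the ground-state
wavefunction (for Cartesian coordinate $\alpha$ of nucleus $\lambda$) with
its magnetic-field derivative (field axis $\beta$), both evaluated at the
reference geometry and zero field.  The tensor is purely imaginary; the
package stores the real coefficient of $i$.

This package evaluates $I^{\lambda}_{\alpha\beta}$ *analytically* for
restricted Hartree–Fock (HF), MP2, CID and CISD wavefunctions, and validates
the result against two independent finite-difference (FD) constructions.

## Wavefunction model

The correlated ground state is the intermediately normalized CI expansion

$$ |\Psi\rangle = |\Phi_0\rangle + \sum_{ia} c_i^a |\Phi_i^a\rangle
  + \tfrac14 \sum_{ijab} c_{ij}^{ab} |\Phi_{ij}^{ab}\rangle , $$

in spin orbitals ($i,j$ occupied; $a,b$ virtual), with the doubles tensor
stored in fully antisymmetrized form.  CID drops the singles; MP2 uses
first-order perturbation amplitudes in place of the CI doubles; HF keeps
only the reference.  "Full normalization" multiplies by
$N = (1 + |c_1|^2 + \tfrac14 |c_2|^2)^{-1/2}$, which adds a correction
term to the AAT involving $N\,\partial N/\partial R$.

The implementation is deliberately spin-orbital (not spin-adapted): the
working equations then mirror the second-quantized derivation term by term,
at a modest memory/speed penalty that is irrelevant at the intended system
sizes.

## How the derivative states are represented

The derivative of the intermediately normalized CI state factorizes exactly
as

$$ \Big|\tfrac{\partial\Psi}{\partial\chi}\Big\rangle
 = \sum_{\mu} \tfrac{\partial c_\mu}{\partial\chi} |\Phi_\mu\rangle
 + \hat T_\chi |\Psi\rangle , $$

where $\hat T_\chi = \sum_{pq} T_{qp}\, a_q^\dagger a_p$ is the one-body
operator of the orbital change.  For a nuclear displacement its matrix is
$A_{qp} = U^R_{qp} + \langle \phi_p^R | \phi_q\rangle$ — the CPHF rotation
plus the half-derivative overlap of the basis functions (the basis moves
with the nuclei); for the magnetic field it is $i\,u^H$ (the basis carries
no field dependence, so no overlap term appears).  The AAT is the bilinear
form of two such states.  Expanding by excitation class gives the familiar
term families — the pure-coefficient-derivative dot products, the
coefficient-derivative × orbital-rotation cross terms, and the fully
orbital part $\langle \hat T_R \Psi | \hat T_H \Psi\rangle$ — whose
doubles–doubles (triples-overlap) block is evaluated through $O(N^3)$ and
$O(N^5)$ intermediates, $X_{be} = \sum_m u^H_{bm} A_{em}$ and
$Y_{ij}^{ab} = \sum_e X_{be} c_{ij}^{ae}$, keeping the whole assembly at
$O(N^5)$.

Every contraction kernel in this assembly is locked, in the test suite,
against a brute-force determinant-algebra oracle that applies
$\hat T_\chi$ explicitly to determinant expansions; the triples-overlap
expansion coefficients were derived from (and are re-verified against) the
same oracle.

## Orbital response: conventions that matter

*Noncanonical perturbed orbitals.*  Only the virtual–occupied block of the
CPHF coefficients is determined by the response equations; rotations within
the occupied and within the virtual space are redundant for a CI wavefunction
(they do not change the variational space).  The package fixes them as
$U_{pq} = -S^\chi_{pq}/2$ for a nuclear perturbation and zero for the
magnetic one.  This removes all orbital-energy denominators inside the
occupied and virtual spaces, so exact or near degeneracies (the test suite
includes the neon atom's degenerate 2p shell) cause no instability.

*Sign conventions.*  Differentiating $C^\dagger S C = 1$ gives
$U^{\chi*}_{pq} + U^\chi_{qp} = -S^\chi_{pq}$ with
$S^\chi = C^\dagger (\partial S/\partial\chi) C$; this is the relation the
package documents and tests (some of the literature defines $S^\chi$ with
the opposite sign).  For the field, $U^{H*}_{pq} + U^H_{qp} = 0$: with
$U^H = i\,u$ purely imaginary, anti-Hermiticity makes the stored real
matrix $u$ *symmetric*.

*Magnetic operator and overall sign.*  The field enters through
$h^{(H_\beta)} = +\tfrac12 L_\beta$ with $L = -i\, (r - O)\times\nabla$
about the gauge origin $O$, without a $1/c$ factor; the stored electronic
AAT is therefore in the "field times $c$" convention in which published
CID/CISD tensors of small molecules have magnitudes of order 0.1–1 a.u.
The absolute sign of the tensor cannot be pinned without a reference
geometry; it is fixed internally by requiring agreement between the
analytic assembly and the complex-arithmetic FD oracle, which share the
operator definition.  `rotatory_strengths()` rescales by $1/c$ before
pairing with the Stephens-convention nuclear tensor
$J^\lambda_{\alpha\beta} = \tfrac{Z_\lambda}{4c}
\epsilon_{\alpha\beta\gamma} R_{\lambda\gamma}$, so the two contributions
combine consistently.

*Gauge origin.*  No GIAOs are used, so all tensors depend on the gauge
origin, which is always the center of mass (most-abundant-isotope masses
from a single embedded table, for bit reproducibility).  Every output
header records origin, normalization, method and frozen-core setting.

*Frozen core.*  One core orbital per non-hydrogen atom is frozen by
default.  Frozen-core runs retain the field-response blocks that couple
core to active-occupied orbitals — with a frozen core those rotations are
physical, not redundant, because they tilt the frozen space — and resolve
them canonically (the core–valence gap is large, so the denominators are
safe).  A frozen-core run with zero frozen orbitals is bit-identical to the
all-electron path.

## Perturbed CI coefficients

No closed-form working equations are assumed for the coefficient
derivatives; they are obtained from the differentiated eigenproblem
projected on the excitation space,

$$ (H - E)\,\partial c = -(\partial H - \partial E)\,c, \qquad
   \partial c_0 = 0, \qquad
   \partial E = \langle c|\partial H|c\rangle / \langle c|c\rangle , $$

with the derivative Hamiltonian assembled from the derivative AO integrals
plus the CPHF coupling terms (for the field, only the one-electron
$\tfrac12 L_\beta$ term is direct, and the couplings carry
$U^\dagger = -i u$ on bra indices, giving commutator structure).  For MP2
the projected first-order amplitude equations are differentiated instead;
with canonical unperturbed orbitals their left-hand side is diagonal.
These solutions are validated against central-difference re-solves in the
*same* orbital gauge (imposing the noncanonically perturbed orbitals on the
displaced problem), and end-to-end through the oracles below.

## The two finite-difference oracles

*Mixed scheme.*  CI coefficient derivatives are formed by central
differences of phase-aligned re-solves at displaced geometries and in a
finite imaginary field, and inserted into the same determinant-derivative
overlap structure; the orbital-rotation matrices are extracted from finite
differences of the MO overlap matrices, so no analytic CPHF enters.  This
validates the response solutions and all derivative integrals.

*Full-numerical scheme.*  The four-point central difference of
nonorthogonal wavefunction overlaps
$\langle \Psi(R\pm h_R) | \Psi(\pm i h_B) \rangle$, evaluated with
generalized Slater rules (determinants of occupied-MO cross-overlap
minors).  Nothing is shared with the analytic assembly beyond the base
integrals, which makes this the most independent check; its naive
double sum over determinant pairs restricts it to the smallest systems.
Complex arithmetic is confined to this module and the field SCF.

## Numerical design choices

Dividing solver errors by $10^{-6}$ steps makes the FD oracles brutally
sensitive to convergence floors.  The package therefore goes well beyond
textbook tolerances:

- **Energy-shifted eigensolves.** Davidson iterations and the
  Rayleigh-quotient refinement operate on $H - E_{\rm ref}$, keeping
  floating-point noise at the correlation-energy scale instead of the
  total-energy scale.
- **Eigenvector refinement.** After Davidson convergence (relative residual
  $10^{-13}$), projected-CG Rayleigh-quotient correction sweeps push the
  absolute residual to the $10^{-12}$–$10^{-14}$ floor.
- **Newton orbital polish.** After DIIS (which stalls near $10^{-12}$),
  orbital gradients are driven below $10^{-14}$ by Newton steps with the
  exact CPHF Jacobian; occupied–occupied and virtual–virtual blocks are
  re-diagonalized so the orbitals (and with them the frozen-core split at
  finite field) are canonical to machine precision.
- **Extended-precision accumulation.** Fock builds, the MO transforms used
  in convergence checks, and the orthonormalization metric are accumulated
  in `long double` in C++; a $10^{-14}$ metric error otherwise couples to
  the orbital-energy scale and floors the gradient near $10^{-12}$.
- **Degenerate-group alignment.** Near-degenerate canonical orbitals (the
  hydrogen-peroxide fixture has a $2.6\times10^{-4}$ a.u. core pair and a
  $6.7\times10^{-4}$ a.u. virtual pair) rotate arbitrarily fast under
  displacement.  Displaced and field-perturbed orbitals are aligned to the
  reference by orthogonal/unitary Procrustes rotations — per degenerate
  group where canonical orbitals are required (HF/MP2), or over whole
  occupied/virtual blocks for CI levels, whose solver accepts any
  orthonormal gauge.  With a frozen core the core block is aligned
  separately so the frozen space remains the canonical core space.
- **Determinism.** There are no stochastic components anywhere; every run
  is bit-reproducible, and orbital phases are fixed by a
  largest-coefficient-positive rule.

With these measures, analytic-vs-mixed-FD agreement at $10^{-6}$ a.u. steps
reaches a few times $10^{-9}$ for water (CID/6-31G, frozen core) and a few
times $10^{-8}$ for (P)-hydrogen peroxide (CISD/6-31G, frozen core; the
residual is FD noise amplified through the near-degenerate core pair — the
same system all-electron agrees to $6\times10^{-9}$).  The two oracles
agree with each other to better than $10^{-9}$ where both run.

## Validation geometries

The fixtures are chosen for their symmetry content, not to reproduce any
external tensor values (which would require the exact geometries behind
them): water at $r_{\rm OH} = 0.96$ Å, $\angle$HOH $= 104.5^\circ$,
oriented with $C_2 \parallel z$ and all atoms in the $yz$ plane — which
forces 17 of the 27 electronic AAT components to vanish, a pattern the
analytic tensor reproduces below $10^{-14}$; (P)-hydrogen peroxide at
$r_{\rm OH} = 0.97$ Å, $r_{\rm OO} = 1.45$ Å, $\angle$OOH $= 100^\circ$,
dihedral $+115^\circ$ (C$_2 \parallel z$, so symmetry-related rows appear
with the characteristic $\pm$ pattern); a skewed hydrogen-molecule dimer
with no spatial symmetry (every tensor component nonzero); H$_2$ and He as
analytic edge cases.  For two-electron systems CISD is full CI, which the
test suite exploits as a dense-diagonalization cross-check.

## Spectrum stage

`rotatory_strengths()` consumes a Cartesian Hessian and an atomic polar
tensor supplied as plain whitespace matrices (these tensors are *inputs*;
the package does not produce correlated force fields — the optional
`fd_hessian_apt()` HF-level generator is a convenience for demonstrations
only).  The mass-weighted Hessian is diagonalized after projecting out
rigid translations and rotations (important off stationary points); modes
below 5 cm$^{-1}$ are dropped.  Per mode,
$R_n = \sum_\beta \big(\sum P\,S\big)_\beta \big(\sum M\,S\big)_\beta$ in
atomic units — the harmonic frequency factors of the electric and magnetic
transition moments cancel — with $M = I/c + J$, converted to
$10^{-44}\,$esu$^2\,$cm$^2$ via the dipole units
$ea_0 = 2.5417\times10^{-18}$ esu·cm and
$e\hbar/m_e = 1.8548\times10^{-20}$ erg/G.  Spectra are sums of Lorentzians
with the default FWHM of $10^{-3}$ eV $= 8.06573$ cm$^{-1}$.

Because the published correlated rotatory-strength tables require external
optimized geometries, Hessians and APTs, the spectrum stage is validated by
its exact invariances instead: a synthetic one-mode system against the
closed form, exact sign reversal under mirror imaging, vanishing rotatory
strengths for achiral planar molecules, and linearity of the broadening.

## What the tests do and do not establish

The suite establishes internal mathematical correctness: derivative
integrals against FD of integrals, CPHF against FD orbitals, response
coefficients against gauge-matched FD re-solves, assembly kernels against
brute-force determinant algebra, and complete tensors against two
independent FD constructions, under the exact study conditions (6-31G,
frozen cores, $10^{-6}$ steps).  It does not establish agreement with any
externally printed tensor entries — those depend on unpublished geometries
— nor the quality of 6-31G AATs as approximations to converged-basis
values, nor anything about non-closed-shell systems, GIAO/gauge-invariant
formulations, or basis sets beyond the shipped library (6-31G for H–Ar
main rows as needed, aug-cc-pVDZ for H and O; Cartesian d functions).

## Problem sizes

The validation systems span 2–22 basis functions, up to 18 electrons, and
CI spaces up to $\sim$30 000 determinants (frozen-core CISD hydrogen
peroxide); a full analytic AAT at that size takes under a minute on one
core, and the mixed FD oracle about the same.  The full-numerical oracle,
whose cost is quadratic in determinant count with a determinant evaluation
per pair, is used up to the hydrogen-dimer CISD space (445 determinants).
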
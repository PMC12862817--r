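# vcdci

Analytic atomic axial tensors (AATs) and vibrational circular dichroism
(VCD) spectra from configuration interaction wavefunctions, in R.

## The problem

VCD — the differential absorption of left- vs right-circularly polarized
infrared light — assigns absolute configurations of chiral molecules, but
its central electronic quantity is awkward: the magnetic dipole transition
moment of a vibrational fundamental vanishes in the Born–Oppenheimer
approximation unless the ground-state wavefunction is differentiated with
respect to both nuclear displacement and magnetic field.  The per-nucleus
electronic object is the atomic axial tensor

    I(λα, β) = < ∂Ψ/∂R_λα | ∂Ψ/∂H_β >,

a purely imaginary mixed second derivative of the ground-state overlap
(the package stores the coefficient of i).  Combined with the nuclear
tensor J = Z/(4c)·ε·R, an atomic polar tensor and a Hessian, it yields
per-mode rotatory strengths

    R_n = Σ_β [Σ P·S]_β [Σ (I/c + J)·S]_β

and hence the VCD spectrum.

`vcdci` computes I analytically for restricted HF, MP2, CID and CISD
wavefunctions: coupled-perturbed Hartree–Fock with noncanonical perturbed
orbitals (no denominators within degenerate occupied or virtual spaces),
perturbed CI coefficients from the differentiated eigenproblem under
intermediate normalization, frozen-core support with the retained
core/active field-response blocks, and O(N^5) contraction intermediates in
the tensor assembly.  Two independent finite-difference oracles — a mixed
scheme (numerical CI-coefficient derivatives inside the analytic
determinant-overlap structure) and a fully numerical scheme (nonorthogonal
determinant overlaps of displaced and complex field-perturbed
wavefunctions) — validate the analytic tensors to 1e-8–1e-9 a.u.  A
self-contained McMurchie–Davidson integral engine (overlap, kinetic,
nuclear attraction, ERIs, angular momentum, nuclear-coordinate derivative
integrals; s/p/d Cartesian Gaussians) makes the package free of external
quantum chemistry dependencies.

Audience: quantum chemists working on chiroptical response methods, and
anyone needing a transparent, fully testable reference implementation of
CI-level AATs at desk scale (a few heavy atoms, double-zeta bases).

## Worked example

Water in its C2v orientation (C2 along z, atoms in the yz plane),
CID/6-31G, frozen oxygen core, fully normalized, center-of-mass gauge:

```r
library(vcdci)
mol <- fixture_geometry("water_c2v")
aat <- aat_analytic(mol, "6-31G", "CID", frozen_core = TRUE)
print(aat)
#> <aat_tensor> CID, full normalization, frozen_core = 1, COM gauge origin
#>               Bx          By         Bz
#> O_1x  0.00000000  0.11588579  0.0000000
#> O_1y -0.19213192  0.00000000  0.0000000
#> O_1z  0.00000000  0.00000000  0.0000000
#> H_2x  0.00000000 -0.04851269  0.0689989
#> H_2y  0.03362577  0.00000000  0.0000000
#> H_2z -0.07470947  0.00000000  0.0000000
#> H_3x  0.00000000 -0.04851269 -0.0689989
#> H_3y  0.03362577  0.00000000  0.0000000
#> H_3z  0.07470947  0.00000000  0.0000000
```

Exactly 17 of the 27 components vanish (below 1e-14 here), the pattern
forced by the C2(z) and σ(yz) selection rules on polar×axial index pairs;
the two hydrogens are related by the C2 rotation, visible in the sign
structure of the Bz column.  The numbers are in atomic units under the
package's documented field convention (perturbation ½ B·L, no 1/c; see the
methods vignette) and are origin- and convention-dependent, which is why
every printed header records method, normalization, origin and frozen-core
setting.

Validating against the mixed finite-difference oracle (steps 1e-6 a.u.):

```r
v <- cmd_validate("water_c2v", "6-31G", "CID", tol = 1e-7)
#> max |analytic - mixed FD| = 3.7e-09
v$pass
#> [1] TRUE
```

A VCD spectrum needs a Hessian and an atomic polar tensor (plain
whitespace matrix files, in a.u.); the per-mode rotatory strengths come
back in 1e-44 esu^2 cm^2 and the Lorentzian spectrum (default FWHM
8.06573 cm^-1) as a data frame:

```r
sp <- cmd_spectrum("hooh_P", "hessian.dat", "apt.dat", method = "CISD")
lorentzian_spectrum(sp)          # wavenumber, intensity
plot_vcd_spectrum(sp)            # ggplot2
```

A thin command-line interface wraps the same functions:

```sh
exec/vcdci aat      --molecule water_c2v --basis 6-31G --method cid
exec/vcdci validate --molecule h2_dimer --method mp2 --tol 1e-6
exec/vcdci spectrum --molecule hooh_P --hessian H.dat --apt P.dat
exec/vcdci fixtures
```

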
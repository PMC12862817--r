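Package: vcdci
Title: Analytic Atomic Axial Tensors and Vibrational Circular Dichroism
    Spectra from Configuration Interaction Wavefunctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the electronic atomic axial tensors (AATs) that govern
    vibrational circular dichroism (VCD) at the Hartree-Fock, MP2, CID and
    CISD levels of theory using analytic derivative methods: coupled-perturbed
    Hartree-Fock response for nuclear-displacement and magnetic-field
    perturbations with noncanonical perturbed orbitals, perturbed CI
    coefficients under intermediate normalization, and assembly of the AAT
    with O(N^5) contraction intermediates and frozen-core support. Two
    independent finite-difference oracles (a mixed scheme with numerical CI
    coefficient derivatives, and a fully numerical scheme built on
    nonorthogonal determinant overlaps of complex field-perturbed
    wavefunctions) validate the analytic tensors. A spectrum stage combines
    electronic and nuclear AATs with atomic polar tensors and a Hessian to
    produce per-mode rotatory strengths and Lorentzian-broadened VCD spectra.
    Includes a self-contained McMurchie-Davidson Gaussian integral engine
    (overlap, kinetic, nuclear attraction, two-electron repulsion, angular
    momentum, and nuclear-coordinate derivative integrals).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
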
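Package: schnorblite
Title: Deep Tensor Networks for Molecular Hamiltonians in a Local Orbital Basis
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: End-to-end prediction of molecular electronic structure in a local
    atomic-orbital basis. A continuous-filter convolutional network with
    angular-momentum pair features predicts Hamiltonian and overlap matrices,
    total energies and analytic atomic forces for molecular geometries, and a
    self-contained extended-Hueckel reference generator with analytic Gaussian
    integrals supplies exactly rotation-covariant training data. From the
    predicted (H, S) pair the package derives orbital spectra, Loewdin
    populations and bond orders, dipole and quadrupole moments, broadened
    densities of states and orbital-energy gradients, and drives Langevin
    molecular dynamics and gradient-based HOMO-LUMO gap optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
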
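Package: sbgx
Title: Structure-Based Gaussian Expansion for Vibrational Eigenstates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-dimensional vibrational eigenstate and nuclear wavepacket
    calculations in a basis of space-fixed multivariate Gaussians placed along
    reaction paths (structure-based Gaussian expansion). Width matrices are
    derived from positive-definitized local Hessians, Hamiltonian matrix
    elements are evaluated in closed form with a local harmonic approximation
    for the potential, and the generalized eigenproblem is solved by canonical
    orthogonalization. Basis sets are built automatically from principal
    component analysis of the reaction path, and potential information at
    basis-pair midpoints can be interpolated by Gaussian process regression
    with leave-one-out cross-validated hyperparameters. Includes analytic
    model potentials, a sinc-DVR reference eigensolver and quadrature oracles
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
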
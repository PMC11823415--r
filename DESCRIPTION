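Package: qcpt2
Title: Stochastic CAS-CI with Imaginary-Time-Averaged Density Matrices and CASPT2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of full configuration interaction
    quantum Monte Carlo (FCIQMC) for complete active space wave functions,
    with three routes to the active-space reduced density matrices (replica
    sampling, hybrid semistochastic histogramming, and pure imaginary-time
    histogramming), fermionic-positivity diagnostics, and a numerically
    stable internally contracted CASPT2 second-order energy built from the
    1-3RDMs and the Fock-contracted 4RDM. Includes deterministic oracles
    (Davidson CI, dense operator algebra, explicit-vector CASPT2) and
    synthetic Hamiltonian fixtures (Hubbard chains, random two-body
    integrals, minimal-basis H2) in FCIDUMP format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
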
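Package: mbar
Title: Multistate Bennett Acceptance Ratio Estimation for Molecular Simulation Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Free-energy estimation from molecular simulation time series with the
    multistate Bennett acceptance ratio (MBAR) estimator. Builds reduced-potential
    matrices for the four common ways simulation data enter the estimator
    (harmonic-restraint umbrella sampling, temperature scaling as in replica
    exchange, neighbor-state accumulation as in alchemical free-energy
    perturbation, and full potential-energy tables including dual-level QM/MM
    reweighting), solves the self-consistent equations by a hybrid of fixed-point
    iteration and Newton-Raphson, reweights to unsampled target states for free
    energies, thermodynamic averages and potentials of mean force, and attaches
    uncertainties by block averaging or bootstrap. Includes a binned WHAM
    reference implementation, synthetic-data generators with analytic or
    quadrature ground truth, delimited-text readers and writers for the
    interchange formats, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
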
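Package: felscape
Title: Free-Energy Landscape Estimation and Path Analysis for Biomolecular Simulation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn energy-tagged reaction-coordinate samples from
    biomolecular simulations into one- and two-dimensional free-energy
    surfaces (per-bin partition functions with LOESS smoothing and bootstrap
    error maps), to extract minimum-energy paths and reaction barriers from
    gridded surfaces (minimax flooding criterion), to estimate free-energy
    differences from constant-velocity steered-pulling work via Jarzynski's
    equality, and to compute trajectory time-series statistics (threshold
    occupancy, stabilized distances, optimal-superposition RMSD). A
    synthetic-data module provides analytic model potentials (harmonic,
    double-well, Mueller-Brown), flat-bottom restraints, overdamped Langevin
    and steered-pulling integrators and Metropolis Boltzmann samplers that
    serve as ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
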
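Package: crimelattice
Title: Monte Carlo Simulation of Spatial Inspection Games with Heterogeneous Punishment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulator for spatial evolutionary inspection games on a periodic
    square lattice. Implements the three-strategy game between ordinary people,
    criminals and punishers, a five-strategy extension with punishers of
    heterogeneous commitment (bearing 1/3, 2/3 or the full punishment cost),
    and a minimal criminal/mild-punisher/strong-punisher model for interface
    dynamics. Strategy imitation follows the Fermi rule under random
    sequential Monte Carlo updating. Provides stationarity detection,
    phase-point classification, parameter sweeps with phase-transition
    enumeration, pairwise invasion experiments, and reproducible replicate
    protocols, with a compiled inner loop and a literal reference
    implementation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
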
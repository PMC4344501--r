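Package: supercoilr
Title: Coarse-Grained Simulation and Shape Analysis of Crowded Supercoiled DNA Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Brownian-dynamics and Monte Carlo simulation of circular DNA
    molecules modelled as torsionally constrained bead-spring rings, together
    with the analyses needed to study their behaviour under physiological
    self-crowding: twist, writhe and linking-number bookkeeping, inertial
    ellipsoid asphericity and prolateness, local intra-molecular thickness via
    a tangent-sphere probe, and enhancer-promoter contact statistics.
    Multi-ring systems evolve under periodic boundary conditions with a
    box-compression protocol to reach target volume occupancy; deterministic
    synthetic conformations (plectonemes, twisted circles, ellipsoid shells)
    support validation of every analysis stage without simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    graphics,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
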
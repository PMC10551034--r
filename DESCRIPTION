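Package: pathFE
Title: Path Collective Variables, Umbrella Sampling and Free-Energy
    Profiles for Ligand Unbinding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Turns a guess ligand-unbinding trajectory into a
    metric-corrected path collective variable over a six-dimensional
    anchor-based descriptor space (one distance, two angles, three
    dihedrals between anchor points on receptor and ligand), samples
    along the path with harmonic umbrella biases driven by a built-in
    Langevin engine or a user-supplied force provider, integrates the
    free-energy profile with the weighted histogram analysis method
    (WHAM), and refines the path toward the minimum free energy path
    with an adaptive string method. Ships analytic toy systems (double
    well, a four-Gaussian two-dimensional benchmark, a rigid host-guest
    complex) with brute-force free-energy oracles so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
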
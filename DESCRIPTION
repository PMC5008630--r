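Package: sfpore
Title: Coarse-Grained Selectivity-Filter Pore Models and Na+/K+ Selectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained bead models of the voltage-gated sodium
    channel selectivity filter carrying DEKA/DERA-type constriction-site
    motifs, samples them with an overdamped Langevin (Brownian dynamics)
    integrator, and analyses the resulting trajectories: axial/radial (Z, R)
    reporter descriptors, linear (SVM) open/closed state classification with
    confidence bands, cation binding-site occupancy, 2D free-energy maps by
    Boltzmann inversion, hydrogen-bond and coordination-shell statistics,
    hierarchical clustering of binding modes, and flat-bottom-restrained
    free-energy-perturbation (EXP/BAR) estimates of relative Na+/K+ binding
    affinity with a thermodynamic-cycle bulk reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
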
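Package: pistonsim
Title: Ensemble Coarse-Grained Simulation and Analysis of Chemoreceptor
    Transmembrane Helices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput coarse-grained molecular dynamics of single
    transmembrane helices in lipid bilayers, built around the bacterial
    chemoreceptor TM2 piston model of signalling. Provides a MARTINI-style
    coarse-grained forcefield and engine (Lennard-Jones and shifted Coulomb
    nonbonded terms, bonded terms and helix dihedral restraints, leapfrog
    integration with Berendsen temperature and semi-isotropic pressure
    coupling), construction of DPPC bilayer and self-assembly systems around
    an ideal helix, per-frame measurement of helix shift, tilt and rotation
    relative to the bilayer, ensemble pooling with circular statistics and
    replica-level bootstrap comparisons of mutants against wildtype, and a
    synthetic-trajectory generator with prescribed shift/tilt/rotation
    distributions for validating every analysis stage without simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    parallel,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
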
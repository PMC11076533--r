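Package: restraintkit
Title: Restraint-Mode Selection and Ensemble Analysis for Steered
    Molecular Dynamics Pulling Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constant-velocity steered molecular dynamics (SMD)
    pulling studies of ligand unbinding. Implements six schemes for
    selecting which protein atoms receive harmonic position restraints
    during pulling (all heavy atoms, all C-alpha atoms, and four
    distance-based C-alpha subsets relative to the ligand and the pulling
    axis), emits GROMACS-style index and position-restraint files, and
    analyses ensembles of pulling trajectories: rupture forces, external
    pulling work, skew-normal force distributions, Jarzynski
    second-cumulant free-energy profiles and unbinding barriers, RMSD,
    protein-ligand contacts, hydrogen bonds, and interaction-energy
    profiles. A coarse-grained overdamped-Langevin toy pulling simulator
    generates synthetic force/displacement/coordinate trajectories with
    the statistical structure the analysis assumes, so every stage can be
    exercised without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    pracma,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
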
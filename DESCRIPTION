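Package: pullfan
Title: Multidirectional Steered Molecular Dynamics Setup and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates constant-velocity steered molecular dynamics (SMD)
    campaigns that probe the mechanical anisotropy of two-body molecular
    complexes. Given a complex in PDB format and two atom selections (a fixed
    group and a pulled group), the package computes the inter-center-of-mass
    pulling axis, generates a labelled fan of unit pulling vectors over a
    (theta, phi) grid covering a hemisphere, and renders ready-to-run NAMD
    and GROMACS input trees with per-replica run scripts. Analysis tools
    parse NAMD SMD log lines and GROMACS pull .xvg output into force traces,
    compute rupture forces, force-distance profiles, replica mean/SD
    ensembles, geometric hydrogen-bond counts and a per-direction anisotropy
    table. A bundled overdamped-Langevin bead-spring simulator with breakable
    interface bonds emits NAMD-dialect SMD logs, so the whole
    setup-run-analyse loop is testable at desk scale without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
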
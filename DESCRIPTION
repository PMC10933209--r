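Package: scamscreen
Title: Aggregation-Propensity Screening of Small Molecules from Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects small colloidally aggregating molecules (SCAMs) from
    molecular dynamics trajectories. Solute molecules are clustered per frame
    by intermolecular atomic contacts under periodic boundary conditions
    (single-linkage at a distance cutoff, minimum-image convention for cubic,
    orthorhombic, truncated-octahedron and general triclinic cells), yielding
    the cluster-count time series N_c, its population profile and the fC_5
    aggregation metric (fraction of frames with fewer than five clusters).
    Also provides an overdamped-Langevin sticky-sphere simulator for
    generating trajectories with tunable aggregation propensity, emitters for
    AMBER-style simulation protocols and box-composition arithmetic, and a
    descriptor-threshold (logD) baseline screen with success-rate scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
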
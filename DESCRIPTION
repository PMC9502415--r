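Package: poregate
Title: Gate Geometry, Ion Permeation and Correlation-Network Analysis for
    Tetrameric Potassium-Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis for G protein-gated inwardly rectifying
    potassium (GIRK) channel simulations: minimum gate distances and
    occlusion classification for the helix-bundle-crossing and G-loop
    gates, ion-conduction event counting by a two-gate state machine,
    lysine-PIP2 salt-bridge statistics with normalized formation and fold
    changes, inter-helix contact totals, typed interaction-distance
    distributions, helix bend and inter-axis angles, backbone dihedral and
    Ramachandran tracking, dynamic cross-correlation matrices with
    thresholded residue networks and k-shortest suboptimal path ensembles,
    and replicate-level statistics (one-way ANOVA, power-based replicate
    sizing). A synthetic-trajectory generator with exact ground truth
    (drifting ions through gated planes, kinked ideal helices, correlated
    residue walks, Bernoulli salt-bridge engagement) makes every stage
    testable without molecular-dynamics data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
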
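Package: hydronet
Title: Internal Hydration-Network Analysis for Class A GPCR Structures and
    Trajectories
Version: 0.1.0
Authors@R:
    person("Hydronet", "Developers", email = "hydronet@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse ordered internal water molecules in G
    protein-coupled receptor (GPCR) structures and molecular-dynamics
    trajectories. Classifies resolved waters into ligand-pocket,
    signalling-network and G-protein-interface regions from hydrogen-bond
    geometry; computes hydrogen-bond episode lifetimes, water-site
    occupancy counts and network rehydration times from multi-model
    coordinate series; detects hydration cavities by a grid-based
    dual-probe method and assigns them to the conserved, junctional and
    extended water cavities by Ballesteros-Weinstein anchor residues;
    scores residue-property conservation at cavity-defining generic
    positions from multiple sequence alignments; and generates fully
    synthetic seven-helix bundle fixtures, two-state occupancy
    trajectories and alignments with known ground truth for estimator
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
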
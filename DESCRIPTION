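Package: kinens
Title: Conformational Ensemble Analysis of Kinase Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ensembles of protein kinase crystal
    structures, developed around the catalytic subunit of cyclic-AMP-dependent
    protein kinase A (PKA). Structures in PDB format are classified into
    ligand-defined catalytic states (substrate/product, inhibitor, apo,
    peptide-only), conformational change is quantified by named C-alpha
    distance triplets spanning the glycine-rich loop, the alpha-C helix, the
    hydrophobic spines and the C-terminal tail, and per-residue flexibility is
    profiled through occupancy-weighted, outlier-filtered, z-score-normalised
    temperature factors (B'-factors). Ensemble-level statistics include
    per-state distance summaries, bootstrap confidence bands on B' profiles,
    principal component analysis of flexibility profiles, kernel density
    estimates of distance distributions and density-based placement of mutant
    structures. A synthetic-structure generator with a ground-truth manifest
    supports fully offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
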
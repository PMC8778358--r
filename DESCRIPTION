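Package: trajpharm
Title: Dynamic Pharmacophores from Molecular Dynamics Interaction Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for trajectory-based virtual screening. Detects
    noncovalent protein-ligand interactions (hydrogen bonds, hydrophobic
    contacts, pi-stacking, salt bridges) frame-by-frame in molecular
    dynamics trajectories, aggregates them into per-residue occurrence
    profiles, derives 3D pharmacophore models from high-occurrence
    interactions, and screens conformer libraries against those models
    with volume and minimum-match filters. Also provides consensus
    clustering of docking poses (complete-linkage RMSD subclusters with
    medoid representatives), backbone RMSD and C-alpha RMSF trajectory
    analytics, salt-bridge prevalence, and seeded synthetic generators
    for pockets, trajectories, pose sets and conformer libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
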
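Package: allodyn
Title: Dual-Modal Classification of Orthosteric and Allosteric Ligands
    from Molecular Dynamics Descriptors and Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and evaluates an uncertainty-aware, dual-branch deep
    classifier that labels protein-ligand complexes as orthosteric or
    allosteric from (i) molecular-dynamics descriptor time series (residue
    pairwise distances and RMSD) and (ii) 2048-bit circular ligand
    fingerprints. Implements the temporal 1D-CNN branch, the binary
    fully-connected branch and the shared head; a dynamic focal loss with
    an epoch-scheduled focusing parameter and entropy regularization;
    AdaBelief optimisation with decoupled weight decay, max-norm
    constraints and Kaiming initialisation; selective classification with
    an "uncertain" abstention class; a fingerprint-to-embedding imputer
    for inference without simulation data; integrated-gradients
    attribution across both modalities; trajectory featurization into
    z-scored 16-row descriptor matrices; and a seeded Ornstein-Uhlenbeck
    synthetic data generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    uwot,
    vegan
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineR,
    ChemmineOB,
    bio3d,
    withr
Config/testthat/edition: 3
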
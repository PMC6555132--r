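Package: sigmaphore
Title: Pharmacophore Modelling and Virtual-Screening Toolkit for Sigma-1 Receptor Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open toolkit for 3D pharmacophore modelling and
    virtual screening, built around sigma-1 receptor ligand
    recognition. Provides a portable JSON pharmacophore format with an
    encoded library of sigma-1 models (structure-derived and literature
    models), geometric ligand-to-pharmacophore matching with excluded
    volumes and rigid or flexible fitting, structure-derived model
    generation from a protein-ligand complex, screening-enrichment
    statistics (enrichment factors, hit rates, ROC-AUC), fingerprint
    diversity analysis, and seeded synthetic benchmark libraries with
    controllable enrichment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    ChemmineR,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
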
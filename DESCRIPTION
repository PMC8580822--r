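Package: gpcrstates
Title: Comparative Analysis of GPCR Activation States from Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of G-protein-coupled
    receptor (GPCR) activation. Selects representative inactive/active
    template structures from an annotation catalog using quality filters,
    detects typed residue-residue contacts keyed by generic residue numbers,
    computes class-wise state-specific contact frequencies with conservation
    filtering, classifies determinant positions into inactivators, activators
    and switches, quantifies transmembrane helix translations and rotations
    between states, maps determinants onto ligand and G-protein interfaces,
    and compares mutant potency/efficacy shifts with an exact Wilcoxon
    rank-sum test. Includes a synthetic-data module that builds ideal helical
    bundles with imposed rigid motions, contact ensembles with programmed
    frequencies, annotation catalogs and mutant signaling tables for fully
    reproducible, download-free analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
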
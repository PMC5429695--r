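Package: cohdock
Title: Structural and Thermodynamic Analysis of Cohesin-Dockerin Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cohesin-dockerin complexes from cellulosome
    assemblies. Reads PDB/mmCIF structures into tidy atom tables, performs
    Kabsch least-squares superposition and rmsd computation with
    alignment-guided residue pairing, assigns secondary structure from
    main-chain hydrogen-bond patterns, detects and classifies inter-chain
    contacts (hydrogen bonds, salt bridges, hydrophobic packing), identifies
    calcium sites and their EF-hand-like coordination-offset patterns,
    tests dockerins for the internal two-fold symmetry that separates
    dual-binding-mode from single-binding-mode modules, and simulates and
    fits single-site (1:1) isothermal titration calorimetry isotherms with
    the standard thermodynamic identities. Includes a synthetic-fixture
    generator producing idealized dockerins with tunable internal symmetry,
    cohesin-like contact plateaus, and noisy titration datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
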
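Package: fqembed
Title: Fluctuating-Charge Polarizable Embedding and UV-Vis Solvatochromism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for solution-phase UV-Vis spectroscopy workflows built on
    polarizable molecular-mechanics embeddings of water. Assembles and solves
    the constrained fluctuating-charge (FQ) and fluctuating-charge-and-dipole
    (FQFmu, with an optional intermolecular charge-transfer variant) linear
    systems under Lagrange charge constraints, evaluates embedding interaction
    energies, generates synthetic solvation droplets with a hydrogen-bonded
    water shell around a carbonyl acceptor, computes radial distribution
    functions and running coordination numbers, broadens per-snapshot stick
    spectra into ensemble-averaged absorption profiles, and evaluates
    vacuum-to-solution solvatochromic shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
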
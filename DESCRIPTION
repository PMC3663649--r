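Package: bindfit
Title: Equilibrium Binding Analysis for Bipartite Nucleosome Recognition
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits equilibrium binding titrations of the kind used to dissect
    multivalent protein-nucleosome recognition: depletion-corrected 1:1
    fast-exchange isotherms fitted globally to NMR chemical shift perturbation
    (CSP) curves, two-state Bloch-McConnell exchange-matrix line shapes coupled
    to a two-equivalent-site (1:2) mass balance, and 2:1 EMSA band-density
    titrations, together with the avidity (effective-concentration) arithmetic
    that links the site affinities to the affinity of the assembled complex.
    Includes seeded synthetic-data generators emulating each experiment,
    profile-likelihood confidence intervals, Sparky-style peak-list and
    plain-text trace readers, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
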
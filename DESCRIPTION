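Package: tropilife
Title: Phylogenetic Comparative Analysis of Lizard Life History and Climate
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogenetic comparative analysis of continuous
    life-history traits when divergence times are unknown: arbitrary
    branch-length schemes (constant, Grafen, Pagel, Nee) with independent
    contrast diagnostics, Blomberg's K randomization test for phylogenetic
    signal, a regression continuum spanning ordinary least squares,
    phylogenetic generalized least squares and an Ornstein-Uhlenbeck
    residual model with AIC/AICc model selection, principal component
    reduction of station climate summaries with an altitude-latitude
    station-matching rule, squared-change and Fitch parsimony ancestral
    reconstruction, and seeded generators for synthetic trees, traits and
    climate matrices emulating a tropical lizard (Tropidurinae) clutch-size
    study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
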
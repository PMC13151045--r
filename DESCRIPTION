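Package: fishplasma
Title: Plasma Protein Binding Refinement of the Fish Plasma Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for read-across environmental risk screening of
    pharmaceuticals with the Fish Plasma Model (FPM). Computes unbound
    fractions (f_u) from rapid-equilibrium-dialysis concentration pairs with
    dilution correction and recovery QC, aggregates replicates and
    laboratories, derives fish:human relative unbound fractions (Rf_u) with
    prioritisation thresholds, predicts original and Rf_u-refined therapeutic
    water concentrations (TWC) from blood:water partitioning, assesses
    conservatism against chronic effect concentrations, and fits generalized
    additive models of molecular predictors of f_u. Ships a 44-pharmaceutical
    screening table and species plasma-pH contexts as a packaged fixture, and
    a seeded synthetic assay generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
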
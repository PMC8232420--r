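Package: diliamw
Title: Screening Drug-Induced Liver Injury Risk from Average Molecular Weight
Version: 0.1.0
Authors@R:
    person("DILI", "Screening Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discriminates drugs with liver-injury (DILI) liability from
    simple constitutional chemical descriptors, centered on the average
    molecular weight (AMW) threshold rule AMW >= 7.4. Provides a molecular
    formula and organic-subset SMILES parser with salt stripping and
    neutralization, constitutional descriptors (AMW, H%, molecular weight,
    Moriguchi logP), a from-scratch CART decision-tree learner with Gini
    importance and cross-validated depth selection, confusion-matrix and
    ROC/AUC statistics, nested cross-validation protocols, ATC-stratified
    screening reports, near-zero-variance and linear-dependence descriptor
    filters with PCA, and a calibrated synthetic cohort generator for
    end-to-end testing without proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
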
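Package: inktqsar
Title: Structure-Immune Modelling of iNKT-Cell Agonist Th1/Th2 Polarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-immune modelling of
    alpha-galactosylceramide (iNKT-cell agonist) analogues. Ingests
    multi-study cytokine measurements (IL-2, IFN-gamma, IL-4, IL-13) across
    five test-systems, normalizes responses to the alpha-GalCer reference,
    condenses them into Derringer desirability scores (Th1/Th2, in vivo and
    in vitro), and relates them to chemical descriptor matrices via stepwise
    multiple linear regression and NIPALS partial least squares with k-fold
    cross-validated Q2. Includes chemical-space analysis (constant-descriptor
    pruning, PCA, average-linkage clustering), test-model variability
    statistics, ROC/AUC evaluation against the reference cutoff, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
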
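Package: fluxweaver
Title: Multi-Condition Integration of Gene Expression into Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling with transcriptome
    integration across multiple experimental conditions. Loads genome-scale
    metabolic models (SBML Level 3 with fbc, or COBRA-style JSON), converts
    them to irreversible form, and solves a mixed-integer linear program that
    maximizes biomass while minimizing the discrepancy between flux
    variability-scaled reaction fluxes and relative gene expression mapped
    through gene-protein-reaction (GPR) Boolean rules. Includes flux balance
    analysis, flux variability analysis, three expression-normalization
    schemes, L1- and L2-regularized two-step variants, accuracy statistics
    against measured fluxes (uncentered Pearson correlation, RMSE/NRMSE),
    reaction-flux flexibility analysis, condition-comparison flux-change
    analytics, and a deterministic generator of toy networks with known
    ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    reticulate,
    quadprog,
    xml2,
    stats,
    tools,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
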
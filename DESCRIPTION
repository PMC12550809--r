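Package: wwbreak
Title: Predicting Micropollutant Breakthrough in Wastewater Treatment from Molecular Structure
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compute per-substance breakthrough (effluent/influent
    concentration ratio) from wastewater treatment plant monitoring campaigns,
    curate the resulting data set with a systematic set of quality criteria,
    featurize chemical structures into molecular fingerprints (MACCS, ECFP,
    path-based, and a biotransformation-rule fingerprint), benchmark a registry
    of regression algorithms under nested cross-validation, train bias-corrected
    random-forest breakthrough predictors, attach per-prediction confidence via
    Tanimoto similarity and ensemble variance, and explain predictions with
    additive substructure attributions. A synthetic-data generator with known
    ground truth supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with rdkit on PATH (used for SMILES
    standardization, InChIKey generation, fingerprints and SMARTS matching)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
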
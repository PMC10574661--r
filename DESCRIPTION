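Package: vscascade
Title: Cascade Ligand-Based Virtual Screening with QSAR Ensembles and
    Self-Organizing Map Activity Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating compound libraries from SMILES or SDF input,
    profiling their chemical space and Murcko scaffold diversity, building
    classification and regression QSAR models on molecular fingerprints and
    2D descriptors under a repeated stratified-split protocol, combining
    fingerprint-specific classifiers by stacked generalization, training
    self-organizing maps on labeled inhibitors to obtain a per-cell
    highly-active proportion (HP) statistic, and running a multi-stage
    virtual screen: consensus classification, averaged-regression potency
    cut, HP cut, and aggregator filtering. A synthetic structure-activity
    generator with known ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    jsonlite,
    randomForest,
    ranger,
    xgboost,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    Rtsne,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel command-line tool (obabel) on the PATH
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
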
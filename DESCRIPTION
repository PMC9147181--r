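Package: rega
Title: Rotation-Ensemble Genetic Algorithm for Molecular Toxicity
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Rotation-Ensemble-GA (R-E-GA) classifier for
    binary molecular toxicity endpoints such as drug-induced liver injury
    (DILI). Candidate solutions encode K feature subsets drawn from a fused
    molecular fingerprint matrix; each subset is rotated in feature space
    (PCA for continuous columns, multiple correspondence analysis for binary
    columns) and used to train an AdaBoost-style chain of weak classifiers
    whose weighted vote yields the prediction. A genetic algorithm evolves
    the subsets against validation F1. The package also provides the
    fingerprint-fusion featurizer (ECFP2, MACCS, a pinned 200-descriptor 2D
    set, and PubChem-style substructure keys), multi-source label curation,
    a repeated train/validation/test evaluation harness with ablation and
    feature-importance analyses, and a synthetic planted-signal data
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
SystemRequirements: OpenBabel command line tool (obabel) for fingerprint
    blocks ECFP2 and MACCS
Config/testthat/edition: 3
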
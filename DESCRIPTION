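Package: severin
Title: Structure-Based Severity Prediction for Factor VIII Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives per-residue structural features (solvent-accessible
    surface area by Shrake-Rupley, backbone dihedrals, hydropathy, B-factor,
    conservation) and residue-interaction-network centralities (including
    Burt's constraint) from a protein structure, builds a PCA-based 20x20
    amino-acid substitution distance index from physicochemical property
    tables, curates clinical hemophilia A mutation records, balances training
    data with ADASYN, trains a cross-validated classifier ensemble that
    outputs a Severity Score in [0,1], calibrates a gray-zone abstention band,
    and scores every possible single-residue substitution in the structure.
    Includes seeded generators of toy structures, property tables and labeled
    mutation sets so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    Matrix,
    igraph,
    randomForest,
    rlang,
    rpart,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
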
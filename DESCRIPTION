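Package: shbpred
Title: Detection and Machine Learning Prediction of Short Hydrogen Bonds
    in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hydrogen bonds between amino acids in protein
    structures using explicit geometric criteria on the donor-acceptor
    heavy-atom separation and the donor-hydrogen-acceptor angle, labels
    each contact as a short hydrogen bond (donor-acceptor distance within
    2.7 Angstrom) or a normal hydrogen bond, and predicts the class of a
    hydrogen bond from 21 categorical structural, chemical and sequence
    features with an ensemble of gradient-boosted decision trees trained
    on undersampled balanced datasets.  Includes PDB reading with quality
    filters, idealized polar-hydrogen placement, Kabsch-Sander secondary
    structure assignment, threshold-tuned precision/recall reporting,
    split-gain feature importance, and a synthetic-data generator for
    labeled feature tables and toy structures with hydrogen bonds planted
    at specified geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    bio3d,
    xgboost,
    Matrix,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
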
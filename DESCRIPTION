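Package: cwlytic
Title: Feature Encoding and SVM Classification of Cell Wall Lytic Enzymes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A protein-sequence feature-engineering and classification toolkit
    for predicting cell wall lytic enzymes (endolysins and autolysins) from
    primary sequence, evolutionary profiles and secondary structure. Implements
    four feature encoders (amino acid composition, dipeptide composition,
    PSSM auto-covariance, and average-chemical-shift auto-covariance), SMOTE
    minority-class balancing, F-score ranking with incremental feature
    selection, an RBF-kernel support vector machine trained by sequential
    minimal optimization with grid search over (C, gamma), and jackknife /
    k-fold evaluation reporting sensitivity, specificity, MCC and accuracy.
    Includes parsers for FASTA, PSI-BLAST ASCII PSSM and PSIPRED ss2 files,
    and a synthetic-data generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
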
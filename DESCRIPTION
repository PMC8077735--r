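Package: carbonylr
Title: Protein Carbonylation Site Prediction with Rotation Forest SVMs
    and Hybrid Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts carbonylation sites on lysine (K), proline (P),
    arginine (R) and threonine (T) residues from protein sequence.
    Peptide windows around candidate residues are encoded as
    distance-based residue (DR) count vectors; the heavily imbalanced
    training sets typical of post-translational modification data are
    balanced by combining SMOTE oversampling of the minority class with
    K-means similarity-based undersampling (KSU) of the majority class;
    classification uses a Rotation Forest ensemble of support vector
    machine subclassifiers with per-feature-subset PCA rotations.
    Includes a full binary-classifier evaluation suite (Sn, Sp, Acc,
    MCC, G-mean, pairwise-rank AUC), stratified cross-validation with
    grid selection over the encoding distance and subset count, a
    seeded synthetic sequence generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
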
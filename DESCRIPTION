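Package: precancell
Title: Ensemble k-NN Classification of Malignant Cells from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies single cells as malignant or non-malignant from their
    transcriptomes. Consensus tumor and non-tumor marker genes are discovered by
    Wilcoxon rank-sum differential expression run independently in several
    labeled reference datasets and intersected across them; a bundled consensus
    marker set (73 tumor and 186 non-tumor marker genes) is included. Each
    labeled reference then drives a k-nearest-neighbor (k = 5) base classifier
    on min-max-scaled marker features, and cells are assigned by majority vote
    across the base classifiers. Includes readers for dense and Matrix Market
    expression matrices, the standard TPM and UMI log-normalizations,
    performance metrics (accuracy, sensitivity, specificity, balanced accuracy,
    AUROC), stratified cross-validation, a negative-binomial simulator with
    planted marker genes, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
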
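Package: ptmkernels
Title: Multiple-Kernel Support Vector Machine Prediction of Protein
    Post-Translational Modification Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-translational modification (PTM) sites on
    serine, threonine and tyrosine residues by combining two precomputed
    kernels in a support vector machine: a min-max normalised BLOSUM62
    similarity kernel over 21-residue peptide windows, and a Gaussian
    interaction-profile kernel computed from a bipartite network linking
    sites to the modifications they are known to carry. Provides repeated
    stratified ten-fold cross-validation with per-fold recomputation of
    the interaction-profile kernel, the standard confusion-matrix metric
    suite (sensitivity, specificity, precision, accuracy, Matthews
    correlation), ROC/AUC, specificity-anchored decision thresholds,
    top-ranked retrieval fractions, probability-ranked candidate lists,
    a synthetic motif-and-network data generator for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    kernlab,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
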
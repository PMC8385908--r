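Package: plipred
Title: Ensemble Deep Learning for Plant lncRNA-Protein Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts interactions between long non-coding RNAs and
    RNA-binding proteins from sequence and secondary-structure k-mer
    features. Implements multi-scale normalized k-mer featurization with a
    reduced seven-group amino-acid alphabet, a stacked denoising
    autoencoder branch with greedy layer-wise pretraining, a
    one-dimensional convolutional branch, Adam followed by SGD
    fine-tuning with dropout and early stopping, and a softmax ensemble
    combiner. Includes confusion-matrix metrics (accuracy, precision,
    sensitivity, specificity, MCC) and ROC AUC, stratified
    cross-validation, a structure-information ablation experiment, a
    synthetic paired-dataset generator with a planted logistic
    interaction signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    data.table,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'alphabets.R'
    'kmer.R'
    'classes.R'
    'train-config.R'
    'nn-core.R'
    'dae.R'
    'branch.R'
    'ensemble.R'
    'encoding.R'
    'sequence-io.R'
    'evaluation.R'
    'synthetic.R'
    'RcppExports.R'
    'cli.R'
    'plipred-package.R'
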
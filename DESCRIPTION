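Package: phenomix
Title: Multi-Omics Phenotype Prediction and Biomarker Discovery with
    Parallel Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates up to three omics layers (gene, miRNA and protein
    expression, DNA methylation, SNP genotypes, copy-number states) measured
    on a shared sample cohort and predicts a categorical or quantitative
    phenotype with a parallel-branch one-dimensional convolutional network
    whose per-omics representations are concatenated into a fully connected
    head. Includes the per-omics encodings (per-sample z-scoring, one-hot
    genotype and copy-number channels, CpG-to-gene filtering), four
    classical baseline models fitted on concatenated feature vectors,
    sequential model-based (Bayesian) hyperparameter search, stratified
    splitting and cross-validated evaluation (ROC/PR, Pearson correlation,
    R squared), gradient-saliency marker ranking with dense ranks and
    marker-to-gene mapping, hypergeometric over-representation analysis of
    marker genes against GMT gene-set collections, and a synthetic
    multi-omics generator with planted differential features so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lhs,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
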
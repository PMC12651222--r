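Package: gatstack
Title: Hybrid Graph-Attention and Random-Forest Classification of
    Multi-Omics Glioma Subtypes on Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-centric integration of mRNA, miRNA and DNA-methylation
    profiles, shared-topology patient graphs over a STRING-style
    protein-protein interaction network, and a hybrid classifier that
    combines a graph attention network (GAT) with a random forest through
    ridge-penalized multinomial logistic stacking. Includes ElasticNet
    feature selection and SMOTE class balancing confined to training folds
    of a repeated stratified cross-validation, attention- and
    importance-based biomarker ranking with per-gene ANOVA annotation, and
    a fully synthetic multi-omics cohort generator with planted
    subtype-discriminative genes so the whole pipeline runs without any
    external download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    randomForest,
    pROC,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
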
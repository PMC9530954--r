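Package: adsubtype
Title: Consensus Molecular Subtyping of Alzheimer's Disease Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for transcriptomic subtype discovery in
    Alzheimer's disease case/control cohorts assembled from multiple microarray
    batches. Implements parametric empirical-Bayes location/scale batch
    adjustment with a PCA-based removal check, resampling-based consensus
    clustering with a cluster-consensus selection rule for the number of
    subgroups, Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg correction and a dual significance threshold,
    subgroup-signature gene set enrichment analysis with phenotype
    permutation and leading-edge hub-gene selection, clinical-trait
    association (pairwise rank-sum, proportion tests, Spearman correlation,
    Kruskal-Wallis, module eigengenes), and an exhaustive diagnostic-panel
    search scoring every non-empty hub-gene subset by logistic-regression
    ROC AUC on held-out samples. A synthetic multi-batch cohort generator
    with planted subtypes, batch effects and coupled clinical traits
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    sva,
    fgsea,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
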
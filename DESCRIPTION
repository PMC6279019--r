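Package: cohortsig
Title: Reproducible Group-Associated Signatures in 16S Microbiota Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage inference pipeline for detecting reproducible
    group-associated signatures (e.g. self-declared ethnicity) in 16S gut
    microbiota cohorts. Implements quality-control filtering of OTU tables,
    taxonomy collapsing, rarefaction with consensus beta-diversity matrices,
    ANOSIM/PERMANOVA distinguishability with subsampling and group-ablation
    ledgers, an adapted BioEnv permutation test, intra-/inter-group distance
    contrasts, ubiquity and abundance/ubiquity stability statistics,
    per-taxon Kruskal-Wallis screening with a cross-cohort replication
    permutation null and taxonomic-redundancy collapsing, covariate
    regressions, imbalance-aware one-vs-all random-forest classifiers
    (SMOTE and downsampling inside cross-validation), family co-occurrence
    clustering, and per-variant Weir-Cockerham FST percentile ranking.
    Ships a synthetic-data generator (Dirichlet-multinomial cohorts with
    planted taxon effects, Balding-Nichols variant panels) so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    pROC,
    sandwich,
    lmtest,
    vcfR,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
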
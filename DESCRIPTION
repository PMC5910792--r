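Package: taxcvi
Title: Identity-Constrained Cross-Validation Benchmarks for Marker-Gene
    Taxonomy Classifiers
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for benchmarking taxonomy prediction on 16S rRNA, ITS and
    other marker-gene reference databases. Implements lowest-common-rank
    (LCR) probability tables, rank identity thresholds, top-hit identity
    distributions, estimation of known and novel OTU counts, test/training
    splits constrained so that every test sequence's top training hit lies
    at a prescribed identity (cross-validation by identity, CVI),
    leave-one-out evaluation, baseline classifiers (global and local
    alignment top-hit, k-mer top-hit, naive-Bayes bootstrap, and a k-mer
    bootstrap classifier with confidence cutoffs), and taxonomy-aware
    accuracy metrics distinguishing over-classification,
    under-classification and misclassification. A synthetic reference
    generator with controlled per-rank divergence makes the whole pipeline
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'classify.R'
    'cli.R'
    'cvisplit.R'
    'identity.R'
    'lcrstats.R'
    'metrics.R'
    'synthgen.R'
    'taxcvi-package.R'
    'taxio.R'
    'utils.R'
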
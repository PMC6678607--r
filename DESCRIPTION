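Package: immunoCohort
Title: Immuno-Cluster Discovery and Systemic Inflammation Association for
    Tumor Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes bulk tumor expression cohorts (triple-negative
    breast cancer being the motivating setting) into immuno-clusters by
    consensus non-negative matrix factorization with cophenetic rank
    selection and a two-step biological refinement, scores the local
    immune state of every sample (ssGSEA enrichment, ESTIMATE-style
    stromal/immune/purity scores, cytolytic activity, tumor inflammation
    signature, aggressive score, immunophenoscore and the integrative
    immune score IMS), estimates immune-cell composition by
    support-vector-regression deconvolution against a user-supplied
    signature matrix, and relates local immunity to systemic blood-count
    inflammation markers (PLR, NLR) through odds ratios, logistic
    regression and nonparametric tests. A synthetic-cohort generator with
    known ground truth backs every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    nnet,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
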
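Package: AssocTestability
Title: Testability of Pairwise OTU Associations in Microbiota Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Closed-form bounds on occurrence-based (Phi coefficient,
    Fisher's exact test) and abundance-based (Pearson, Spearman)
    association statistics as functions of OTU prevalence, and the
    classification of OTU pairs by whether positive and negative
    associations can ever reach significance at a given sample size.
    Includes prevalence-distribution models (uniform grid, truncated
    power law with maximum-likelihood fitting), a Gaussian-copula
    simulator of zero-inflated count communities with a known signed
    association structure and a target-condition-number correlation
    matrix, association-measure response surfaces, testability-masked
    sparse inverse-covariance network inference on centered log-ratio
    transformed counts, and sign-resolved AUC/AUPRC benchmarks of
    edge recovery under alternative data-filtering strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    biomformat,
    jsonlite,
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
biocViews: Microbiome, NetworkInference, Software, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
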
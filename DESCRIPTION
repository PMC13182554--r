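Package: odorstrength
Title: Ordinal Odor Strength Modeling from Molecular Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating ordinal odor-strength
    predictors from molecular structure. Provides a synthetic two-source
    dataset generator with a latent mass-transport model, curation of
    free-text and categorical strength annotations onto a four-level
    ordinal scale with chance-corrected agreement statistics
    (quadratically weighted Cohen's kappa, ordinal Krippendorff's alpha),
    molecular descriptor and fingerprint featurization, Tanimoto-grouped
    leakage-aware stratified splitting, direct and hierarchical ordinal
    classifiers including a rank-consistent cumulative-logit (CORAL)
    learner and a descriptor ensemble, macro-averaged ordinal evaluation
    metrics, 5x2cv paired t-tests, descriptor-space analysis (PCA,
    clustering agreement), and Shapley-value feature attribution with
    correlation-clustered feature groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    nnet,
    ranger,
    xgboost,
    mclust,
    cluster,
    pROC,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
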
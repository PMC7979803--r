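Package: vaen
Title: Drug-Response Imputation from Bulk Transcriptomes via Variational
    Autoencoder Latent Spaces and Elastic Net Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes anticancer drug response from bulk gene-expression
    profiles. Expression matrices are rank-normalized, compressed with a
    pool of independently seeded variational autoencoders, and per-drug
    Elastic Net models are trained on the latent representations; the
    best autoencoder for each drug is selected by mean holdout R-squared
    under cross-validation. Trained models transfer to new cohorts
    (including microarray data, via rank normalization) to impute
    response for unscreened samples. Includes linear baselines
    (gene-level and PCA-compressed Elastic Net), a downstream
    association battery (extreme-group enrichment, mutation and
    mutation-cluster tests, tumor mutational burden comparisons,
    expression trend tests with Stouffer combination, drug-class
    enrichment, and mutation-by-pathway interaction models), and a fully
    seeded synthetic-data generator that realizes the decomposition of
    drug response into an expression-regulated component plus
    independent components, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
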
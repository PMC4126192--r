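Package: wlassoqtl
Title: Probabilistic Genotype Imputation and Weighted Lasso for QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step QTL mapping for biparental populations with binary
    genotypes (recombinant inbred lines, backcrosses, double haploids).
    Missing marker genotypes are imputed from a flanking-marker probability
    model whose recombination-rate parameters are estimated by pseudo maximum
    likelihood; the imputation probabilities yield per-entry certainty
    weights that a weighted lasso propagates into sparse marker selection
    with BIC tuning. Includes the standard baselines (nearest-marker
    imputation, multiple-regression scan, ordinary and adaptive lasso),
    per-marker LRT/LOD scoring, and an Ising-chain simulation harness with
    MCAR/MAR missingness and ROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    yaml
Config/testthat/edition: 3
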
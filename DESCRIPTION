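Package: docility
Title: Genetic Evaluation of Ordinal Temperament Scores in Beef Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic evaluation of subjectively scored, heavily
    skewed ordinal temperament records in beef cattle. Implements record
    editing and contemporary-group construction, pedigree (A), genomic (G)
    and blended single-step (H) relationship matrices, Bayesian threshold
    (liability) animal models with maternal genetic and maternal
    environmental effects fitted by Gibbs sampling, liability-scale
    heritabilities, LR-method forward validation (bias, dispersion,
    accuracy), accuracy-weighted correlations between breeding-value sets,
    and weighted single-step GWAS with sliding-window decomposition of the
    additive genetic variance. A synthetic-data module generates pedigrees,
    genotypes and ordinal phenotypes with the assumed statistical structure
    so the whole pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
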
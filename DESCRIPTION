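Package: tetraGS
Title: Genomic Selection with Tetraploid Allele Dosage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage genomic selection pipeline for autotetraploid outcrossing
    species evaluated in half-sib polycross trials. Simulates polycross
    populations with tetrasomic inheritance and GBS-like read depths, calls
    integer allele dosages (0-4) from biallelic read counts with an EM binomial
    mixture, fits longitudinal linear mixed models with structured
    variance-covariance matrices across harvests by REML, builds pedigree (A),
    genomic (K) and blended (K*) relationship matrices for tetraploids, fits six
    dosage-aware whole-genome prediction models (Bayesian ridge regression,
    BayesA, BayesB, BayesC, Bayesian LASSO via Gibbs sampling, and REML GBLUP),
    and evaluates them by replicated k-fold cross-validation, including the
    comparison of tetraploid versus diploidized dosage coding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
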
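Package: gallop
Title: Fast Genome-Wide Association Analysis of Longitudinal Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis of longitudinal outcomes with a
    random-intercept-and-slope linear mixed model. Variance components are
    estimated once on the SNP-free reduced model; each SNP is then scored by
    solving a bordered penalized least-squares (Henderson) system whose core
    factorization is precomputed and reused, yielding cross-sectional and
    SNP-by-time interaction estimates, standard errors and Wald p-values at a
    small fraction of the cost of refitting a mixed model per SNP. Includes a
    dense exact solver used as an internal oracle, a simulation module for
    longitudinal GWAS data, an accuracy-study harness comparing the fast scores
    against full per-SNP REML refits, and chunked text/binary dosage input for
    genome-scale scans.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
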
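Package: rhepcg
Title: Genomic Prediction Without Direct Inversion of the Genomic
    Relationship Matrix
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction for large training populations by combining
    randomized Haseman-Elston regression (a method-of-moments heritability
    estimator made O(nm) by Hutchinson trace estimation) with a matrix-free
    preconditioned conjugate gradient solver for the SNP-BLUP mixed-model
    equations, so the genomic relationship matrix is never formed or
    inverted. Includes a conventional GBLUP baseline (profile REML on the
    GRM eigenbasis plus direct BLUP), an F2 population simulator with
    controlled heritability, and a replicated train/candidate evaluation
    harness reporting heritability estimates and predictive accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
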
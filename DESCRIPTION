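Package: loopwalk
Title: Loop-Walking Mutant Screens and In Silico Triple-Mutant Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for thermostability screens of three-residue
    loop mutants ("loop walking"): physicochemical encoding of residue
    triples with AAindex-style descriptor scales, residual-activity
    arithmetic and quadrant classification of screening data, tertile
    stratification, a two-stage L1-penalized logistic discrimination
    cascade with leave-one-out validation, exhaustive enumeration and
    probability ranking of unobserved triple mutants, and a synthetic
    screen generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
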
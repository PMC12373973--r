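Package: revsig
Title: Reversal Scoring of Disease Expression Signatures for Drug
    Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Connectivity-map style drug repurposing toolkit. Builds
    disease signatures from differential-expression tables, scores
    drug-response expression profiles for signature reversal with a
    Kolmogorov-Smirnov statistic (RGES) summarized per drug across
    treatment conditions (sRGES), ranks mechanism-of-action drug classes
    by enrichment at the reversal end of the sRGES ranking, identifies
    class-level and sensitivity-associated reversal genes with rank-based
    tests, and links predicted reversal to phenotypic drug response via
    plate normalization and four-parameter logistic dose-response fits.
    A synthetic-data generator with planted ground truth makes the whole
    pipeline testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
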
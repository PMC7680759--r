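Package: ciscreen
Title: Plate-Based Screening Statistics for Chemical Suppression of
    Cytoplasmic Incompatibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for plate-based egg-hatch screens that test
    chemical suppression of Wolbachia-induced cytoplasmic incompatibility
    (CI) in Drosophila. Provides a well-level data model for egg-hatch
    records, a calibrated beta-binomial simulator of screening plates,
    plate quality-control gating and dose-response tolerability scoring,
    an adaptive two-sample testing procedure (Shapiro-Wilk and Levene
    screening into t, Welch t, Mann-Whitney U, or a bootstrap t) with
    Bonferroni-scaled alpha and Yes/Borderline/No hit classification,
    Z-prime assay-quality scoring with hit-range normalization, and a
    bootstrap sub-sampling procedure that estimates the minimum number of
    replicate wells needed per condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    car,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
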
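Package: epirisk
Title: DNA-Methylation EpiScore Projection and Fitness-Mediated Disease Risk Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes protein EpiScores as weighted linear combinations of CpG
    methylation beta values, runs covariate-adjusted association scans between
    physical-fitness traits and EpiScores, links significant associations to
    external EpiScore-disease log hazard ratios, and derives patient-level
    composite disease risk scores combining a direct (EpiScore x log HR) term
    with an indirect product-of-coefficients term propagating fitness effects
    through EpiScores. Includes cohort-relative z-score normalization with
    top-decile high-risk flagging, age- and sex-stratified fitness
    categorization, ranking of multi-flagged patients, and validation of risk
    scores against an external cardiovascular-disease EpiScore benchmark.
    A synthetic cohort generator with planted fitness effects and a
    projection-consistent methylation matrix makes the full pipeline testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
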
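Package: misinfoK
Title: Misinformation Vulnerability Scoring and Subgroup Inference for
    Messaging-App Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the vulnerability of survey respondents to
    health misinformation circulated on peer-to-peer messaging platforms.
    Implements a rubric-based per-respondent vulnerability index K (the ratio
    of a respondent's summed rubric score to the maximum achievable score),
    demographic subgroup stratification by age and occupation, subgroup
    inference via one-way analysis of variance with Hochberg GT2 post hoc
    comparisons built on the studentized maximum modulus distribution,
    Hartley's F-max variance-homogeneity screen with Monte-Carlo calibration
    for unequal group sizes, and a pooled two-proportion z-test comparing the
    perceived credibility of false messages with and without attached
    background evidence. A synthetic-cohort generator with a latent
    vulnerability trait and an additive belief model makes the full pipeline
    testable end to end, including parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
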
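Package: latebloom
Title: Time-Dependent Biomarker Analysis of Late Recurrence in
    ER-Positive Breast Cancer
Version: 0.1.0
Authors@R:
    person("latebloom", "developers", email = "latebloom@example.org",
           role = c("aut", "cre"))
Description: Gene-expression signature scoring (proliferation and
    estrogen-related scores), median-split biomarker grouping, landmark
    survival analysis with proportional-hazards diagnostics, kernel
    hazard-rate estimation, and neoadjuvant molecular-response analysis
    for ER-positive breast cancer cohorts, together with a synthetic
    cohort generator with piecewise-constant group-specific hazards for
    end-to-end testing without access to the original microarray series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
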
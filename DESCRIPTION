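Package: vespre
Title: Simulation and Analytics for an EHR-Embedded Sepsis Biorepository Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of a virtually
    enabled biorepository pipeline for sepsis: a seeded emergency-department
    event-stream simulator with known ground truth; a digital sepsis-3
    screening alert built on six criteria including modified SOFA organ
    dysfunction elements, plus a full-SOFA adjudication oracle; an enrollment
    funnel with a daily cap, a three-reason exclusion cascade and a
    de-identification crosswalk; remnant-specimen eligibility and aliquot
    accounting for the biorepository; cent-exact comparative study-cost
    accounting; and proof-of-concept cohort analytics (missingness filter,
    log-fold biomarker matrices, an eigenvalue factor screen, and an OPTICS
    reachability diagnostic recommending a clustering family).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
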
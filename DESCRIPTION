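Package: plantdex
Title: Plant-Based Diet Quality Indices and Chronic Kidney Disease in a
    Complex Survey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ingredient-level construction of three plant-based diet quality
    indices (overall PDI, healthy hPDI, unhealthy uPDI) from 24-hour recall
    data, with a core/discretionary consumption context, survey-weighted
    quintile scoring over 23 food groups, rule-based chronic kidney disease
    and comorbidity classification, and survey-weighted regression with
    delete-a-group jackknife replicate-weight variance. Includes a synthetic
    national-nutrition-survey cohort generator so that the full pipeline,
    calibration checks and parameter-recovery experiments run without access
    to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
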
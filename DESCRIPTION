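Package: nephest
Title: Nephron Number Estimation from Kidney Biopsy Morphometry and Renal
    Cortex Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating an individual's total nephron (glomerular)
    number from needle-biopsy morphometry combined with a renal cortex volume,
    including tissue-shrinkage and small-profile detection-cutoff corrections;
    computation of whole-kidney and cortex volumes from tomographic slice
    areas; construction of composite renal endpoints (mortality, renal death,
    adjudicated cerebro-cardiovascular events, 50% eGFR reduction) and annual
    eGFR decline rates from enrollment and follow-up registries; and a
    two-group log-rank sample-size design under exponential event times with
    uniform accrual, with Monte-Carlo verification of power and type-I error.
    A synthetic-data engine provides virtual kidneys, biopsy-section sampling,
    ellipsoid tomography phantoms and full simulated cohorts for validation.
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
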
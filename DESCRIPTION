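Package: coctraj
Title: Continuity-of-Care Trajectory Modelling for Longitudinal Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying long-term continuity-of-care patterns in
    administrative health-insurance claims. Computes the Bice-Boxerman
    Continuity of Care Index (COCI) per patient-year and the updated (2011)
    Charlson Comorbidity Index from ICD-10 codes, fits censored-normal
    group-based trajectory models to annual COCI series by multi-start EM,
    selects the number and shape of trajectory groups with BIC, group-share
    and average-posterior-probability rules, and relates trajectory group
    membership to annual medical expenses by covariate-adjusted linear
    regression. A synthetic claims generator with known group structure
    supports end-to-end validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
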
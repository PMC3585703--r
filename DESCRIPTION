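Package: gestage
Title: Gestational Age Dating, Agreement Statistics and Perinatal Cohort
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining gestational age (GA) at birth from
    multiple imperfect sources: last menstrual period (LMP), ultrasound
    examinations grouped into gestational windows, and the Capurro neonatal
    maturity exam.  Implements birthweight-for-GA Z-scoring against a
    sex-specific intrauterine growth reference with outlier exclusion, a
    hierarchical best-estimate assignment algorithm with outlier-based
    fall-through, and a full agreement-evaluation battery (Cohen's kappa
    with Landis-Koch interpretation bands, sensitivity, specificity,
    predictive values, chi-square rate comparisons, and day-difference
    discrepancy tables).  Includes a configurable synthetic-cohort
    generator emulating the measurement-error structure of self-reported
    menstrual dating (including calendar month-slip recall errors),
    window-specific ultrasound error, and the systematic pull-toward-term
    bias of neonatal maturity exams, so every pipeline stage is testable
    without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
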
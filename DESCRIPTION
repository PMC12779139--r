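Package: careflow
Title: Process Mining of Surgical Care Pathways from Administrative Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and compare hospital care pathways from
    administrative inpatient and outpatient records, using the diagnostic
    segment of the breast cancer surgical pathway (last biopsy to surgery) as
    the worked case. Provides a synthetic administrative-record generator,
    ICD-9-CM cohort selection with explicit exclusion accounting, event-log
    construction at day granularity, directly-follows process-map discovery
    with frequency, performance and mixed views and importance zooming,
    waiting-time and guideline-adherence statistics, and per-hospital
    cost-variation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    xml2,
    withr,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
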
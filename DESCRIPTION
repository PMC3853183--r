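Package: casemixr
Title: Case-Mix Adjusted Efficiency and Effectiveness Profiling for Primary Care Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling primary health care centres and basic care
    teams with case-mix (morbidity-burden category) adjustment. Implements
    indirectly standardized efficiency indices for costs, visits and care
    episodes (observed over expected means), a case-mix risk index, a 0-100
    composite effectiveness score aggregated from care-quality indicators,
    and the correlation analysis relating efficiency, complexity and
    effectiveness across units. Includes a seeded synthetic cohort generator
    that emulates the morbidity-category mixture and per-category utilization
    moments of a large Catalan primary-care population, with plantable
    unit-level complexity, efficiency and quality effects for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
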
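Package: rxflow
Title: Prescription and Dispensation Registry Analytics for Adherence and
    Persistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing national e-prescription registries of
    chronic cardiovascular medication, with statin therapy as the worked
    case. Converts prescription and dispensation claims into tablet-
    standardised weekly utilisation series, builds per-patient medication
    supply timelines with refill carryover, computes Medication Possession
    Ratio (MPR) adherence, detects therapy discontinuation under a grace
    period and estimates Kaplan-Meier persistence, and relates dispensing
    dynamics to weekly COVID-19 surveillance counts and lockdown calendars.
    Includes a synthetic registry generator that emulates the statistical
    structure of payer claims data (accrual, pack-size mix, primary
    non-adherence, dispensing delays, discontinuation hazards, seasonal and
    lockdown effects) so the full pipeline is testable without access to
    confidential source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
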
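Package: patientday
Title: Build Patient-Facility-Day Datasets from Multi-Hospital EHR Extracts
Version: 0.1.0
Authors@R: person("VAPD", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms raw multi-hospital electronic health record extracts
    (specialty transfers, laboratory results, vital signs, barcode medication
    administrations, and diagnosis/procedure codes) into a standardized
    patient-facility-day dataset. Reconstructs the nesting of specialty stays
    into bedded stays, single-site hospitalizations, acute hospitalizations and
    episodes of care; harmonizes laboratory tests and vital signs across
    facilities by LOINC code and local test name; derives daily medication
    indicators from free-text drug names; computes daily SOFA organ-dysfunction
    subscores, claims-based (Angus) and EHR-based (CDC Adult Sepsis Event)
    sepsis phenotypes, and hospitalization-level outcomes. Includes a synthetic
    EHR generator with known ground truth so the full pipeline is testable
    without access to protected clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
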
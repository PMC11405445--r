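Package: hoicost
Title: Analogy Costing of Hospital-Onset Infection Attributable Costs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the attributable direct medical cost of hospital-onset
    infections from hospital discharge data using an analogy costing
    framework. Discharges with an infection as the principal diagnosis serve
    as cost analogs for the same infection acquired in hospital (coded as a
    secondary diagnosis). The pipeline builds principal, secondary and
    matched no-infection cohorts from ICD-9/ICD-10 code catalogs, converts
    charges to costs with cost-to-charge ratios, fits stage-1 median (L1)
    regressions of cost on patient and facility covariates, transfers the
    fitted coefficients to the secondary cohort to obtain mean attributable
    costs with a length-of-stay decomposition, and aggregates the estimates
    against national incidence tables to produce burden-weighted totals.
    Includes a seeded synthetic discharge-record generator emulating the
    statistical structure of the National Inpatient Sample so that every
    stage is testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
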
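Package: tzdsafety
Title: New-User Cohort Pharmacoepidemiology of Antidiabetic Drug Safety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for comparative drug-safety
    studies of antidiabetic medication in longitudinal primary-care records:
    a synthetic electronic-health-record generator with known ground truth,
    inception (new-user) cohort construction with matched controls,
    time-dependent classification of drug exposure into current, recent and
    past person-time (preventing immortal time bias), Poisson incidence-rate
    models with person-time offsets, kernel-smoothed hazards over duration
    of use, Kaplan-Meier life tables with excess-risk differences, and
    cause-of-death tabulation by ICD-10 chapter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
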
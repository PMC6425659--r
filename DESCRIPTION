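Package: carepath
Title: Care Pathways and Outcomes After Ambulance Attendance for Mental
    Health Emergencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing coded care pathways from linked
    ambulance, emergency-department, inpatient and death records, selecting
    an index cohort of mental-health and self-harm emergency calls,
    quantifying repeat attendance, emergency-department self-discharge and
    one-year mortality, and assembling disclosure-controlled summary
    tables. Includes a seeded synthetic linked-record generator calibrated
    to published national distributions so the whole pipeline can be
    exercised and tested without access to any real health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
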
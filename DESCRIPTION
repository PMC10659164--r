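Package: biobankDQ
Title: Rule-Based Data-Quality Assessment for Multicenter Biobank Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Declarative data-quality assessment for clinical-epidemiological
    data collected by multicenter biobank networks. Implements a DQ4HEALTH-style
    validation-rule engine over four quality dimensions (completeness, validity,
    accuracy, uniqueness) with error/warning severities, per-institution
    aggregation and error-rate reporting, institution profiling
    (omission-dominant versus mapping-dominant sites), chi-square independence
    tests and correlation of error counts with institutional factors. Ships a
    synthetic multi-institution data generator with controlled error injection
    and a ground-truth ledger so the whole pipeline is testable without access
    to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
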
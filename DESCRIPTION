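Package: rdikit
Title: Regularity Disruption Index and Home-Cage Activity Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Regularity Disruption Index (RDI), a sample-entropy
    based digital biomarker for rest and sleep fragmentation in minute-binned
    home-cage locomotor activity, together with companion circadian activity
    metrics (weekly day/night activity, smoothed 24 h profiles, least-active-hour
    statistics, late-stage decline slopes, cross-correlation lag between group
    curves), group statistics with correlation-aware D/AP multiplicity
    correction, and a seeded simulator of home-cage activity with configurable
    disease-progression effects for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
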
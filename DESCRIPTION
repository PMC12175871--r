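Package: prhism
Title: Scoring and Rater-Agreement Analysis for Health-Information Quality Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of inter-rater and intra-rater agreement on
    ordinal health-information quality instruments. Implements scoring for the
    PRHISM (13 principles, 0-4) and DISCERN (16 items, 1-5) instruments
    including not-applicable handling and the 0-100 score conversions, expert
    accuracy/harm recoding, weighted and unweighted Cohen kappa with
    large-sample standard errors and normal-approximation confidence
    intervals, pairwise-averaged multi-rater agreement with a delete-one-video
    jackknife interval, the kappa z-test, two-way random-effects intraclass
    correlation, Landis-Koch interpretation bands, a latent copy-model
    simulator for ordinal ratings with a calibrated population kappa,
    simulation-based power and minimum-sample-size search for agreement
    studies, a synthetic study-dataset generator (video catalog, exclusion
    filtering, multi-instrument ratings), and a pipeline that runs the full
    reliability and validity analysis suite and writes results tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
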
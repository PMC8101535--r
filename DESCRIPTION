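Package: smokehia
Title: County-Level Health Impact Assessment of Wildfire Smoke PM2.5
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates excess mortality attributable to elevated fine
    particulate matter (PM2.5) during wildfire smoke episodes from
    monitor-level readings. Builds county-day exposures (nephelometer
    recalibration, within-county averaging, neighbor imputation against a
    matched baseline window), computes attributable fractions under a
    concentration-response function of total PM2.5 and under an odds ratio
    of wildfire smoke days, annualizes the episode for chronic burden,
    models avoided mortality under proportional exposure-reduction
    interventions (including poverty-targeted air-cleaner programs with
    costing), and propagates within-county spatial exposure uncertainty by
    log-normal Monte Carlo simulation. Includes a synthetic study
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
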
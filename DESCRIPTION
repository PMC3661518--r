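Package: pmslt
Title: Proportional Multi-State Life Table Cost-Effectiveness Modelling of
    Bariatric Surgery
Version: 0.1.0
Authors@R:
    person("pkg", "maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A proportional multi-state life table (Barendregt-style) model
    for evaluating population-level weight-loss interventions, built around
    laparoscopic adjustable gastric banding (LAGB) surgery in an
    Australian-type adult population. Converts a lognormal body-mass-index
    exposure distribution and per-unit relative risks into potential impact
    fractions, runs per-disease illness-death life tables and a master
    cohort life table to compute DALYs averted, applies intervention costs
    and disease cost offsets to produce net costs and ICERs with dominance
    handling, and propagates parameter uncertainty with Monte Carlo
    simulation. Includes a synthetic-data generator that emulates the
    structure of burden-of-disease inputs so the full pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
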
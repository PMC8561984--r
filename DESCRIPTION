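Package: equicat
Title: Concentration Index, Horizontal Inequity and Benefit Incidence
    Analysis for Household Health Surveys
Version: 0.1.0
Authors@R:
    person("Equicat", "Developers", email = "equicat@example.org",
           role = c("aut", "cre"))
Description: Tools for socioeconomic health-equity analysis of
    individual-level household survey data: adult-equivalent consumption
    ranking and weighted fractional ranks, concentration indices for
    binary utilization outcomes with Wagstaff and Erreygers corrections,
    decomposition of inequality into need and non-need contributions via
    a linear approximation of a probit model, horizontal inequity through
    indirect need standardization, and benefit incidence analysis of
    health subsidies net of out-of-pocket payments. Ships a calibrated
    synthetic household-survey generator so every estimator can be tested
    against known ground truth.
License: MIT + file LICENSE
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
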
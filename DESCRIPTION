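Package: glp1sim
Title: Cost-Effectiveness Microsimulation of GLP-1 Receptor Agonists in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event annual-cycle microsimulation of long-term diabetes
    outcomes for six GLP-1 receptor agonists added to metformin, from a Chinese
    healthcare-system perspective. Provides a parameter table with uncertainty
    distributions, a Bayesian random-effects network meta-analysis of 6-month
    change rates in HbA1c, BMI and blood pressure (with Gelman-Rubin,
    node-splitting and design-by-treatment diagnostics), calibrated synthetic
    risk equations standing in for the CHIME risk engine, cost and QALY accrual
    with discounting, deterministic and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, scenario horizons, and a
    generalized linear model relating HbA1c/BMI control to comorbidity burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
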
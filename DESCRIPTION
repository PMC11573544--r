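Package: ucmarkov
Title: Markov Cohort Cost-Effectiveness Model for First-Line Nivolumab
    plus Gemcitabine-Cisplatin in Advanced Urothelial Carcinoma
Version: 1.0.0
Authors@R:
    person("Health Economics", "Modelling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) Markov cohort
    model evaluating the cost-effectiveness of first-line nivolumab plus
    gemcitabine-cisplatin versus gemcitabine-cisplatin alone in advanced
    urothelial carcinoma from a Chinese payer perspective.  Includes
    reconstruction of pseudo individual-patient data from digitized
    Kaplan-Meier curves with numbers-at-risk tables, maximum-likelihood
    fitting of five parametric survival families with AIC-based selection,
    per-cycle transition matrices combining trial hazards with background
    mortality, discounted half-cycle-corrected accrual of life years, QALYs
    and costs, incremental analysis (ICER, net monetary benefit),
    price-threshold search, one-way (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and a calibrated
    synthetic-data generator emulating the CheckMate 901 survival summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
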
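# ucmarkov

A Markov cohort cost-effectiveness model for first-line **nivolumab plus
gemcitabine–cisplatin versus gemcitabine–cisplatin alone** in advanced
(unresectable or metastatic) urothelial carcinoma (aUC), from a Chinese payer
perspective. The package is aimed at health-economics analysts who want a
fully scripted, testable version of this evaluation: every stage — from
digitized Kaplan–Meier coordinates to the cost-effectiveness acceptability
curve — is an R function with a documented contract.

## The model

Three health states: progression-free survival (PFS), progressed disease
(PD), and death. A cohort starts in PFS at age 65 and is propagated through
522 weekly cycles (a 10-year horizon) by per-cycle 3×3 transition matrices.

* **Survival inputs.** Published KM curves are consumed as digitized
  `(time, survival)` coordinates plus numbers-at-risk tables; pseudo
  individual-patient data are reconstructed by Guyot-type interval
  accounting (`reconstruct_ipd()`), then five parametric families
  (exponential, Weibull, lognormal, log-logistic, Gompertz) are fitted by
  right-censored maximum likelihood and the extrapolation model is chosen by
  AIC (`fit_all_families()`, `select_by_aic()`).
* **Transition probabilities.** For a fitted curve S, the per-cycle event
  probability over `(t−u, t]` is `tp(t, u) = 1 − S(t)/S(t−u)`. The death
  probability is floored by age-specific background mortality from a life
  table, and the PD death rate is solved each cycle so the modelled
  all-state survival tracks the fitted OS curve (`build_schedule()`).
* **Accrual.** Life years, QALYs (utilities 0.80 in PFS, 0.71 in PD) and
  costs accrue with trapezoidal half-cycle correction, discounted at 5%/year
  at cycle midpoints (`run_cohort()`). Costs cover drug acquisition with
  whole-vial wastage (nivolumab $1249.072/100 mg; gemcitabine $5.596/0.2 g;
  cisplatin $1.059/10 mg; chemotherapy dosed on a Du Bois body surface area
  for 65 kg / 1.65 m), administration fees, one-time adverse-event costs, a
  second-line gemcitabine–cisplatin course on progression, and terminal
  care.
* **Decision metrics.** Incremental cost-effectiveness ratio
  (ICER = ΔCost/ΔQALY) against a willingness-to-pay (WTP) threshold of
  $38,223/QALY (3× 2022 Chinese per-capita GDP), net monetary benefit,
  one-way (tornado) sensitivity analysis, a 5,000-draw probabilistic
  sensitivity analysis with Gamma/Beta distributions and the CEAC, and a
  bisection search for the nivolumab price reduction that reaches the WTP
  (`incremental()`, `owsa()`, `psa()`, `ceac()`, `price_threshold()`).
* **Synthetic data.** Because the trial's raw data are not public, a
  calibrated generator (`trial_calibrations()`, `calibrate_family()`,
  `simulate_ipd()`, `emulate_digitized_curve()`, `make_life_table()`)
  reproduces the printed CheckMate 901 summaries — median OS 21.7 vs 18.9
  months, median PFS 7.9 vs 7.6 months, with their 95% CIs — so the whole
  pipeline runs and is tested offline.

## Worked example

```r
library(ucmarkov)

model <- build_cea_model_calibrated()   # survival models from the printed medians/CIs
res <- evaluate_model(model)
res$nivo
#> <cea_outcomes> LY 2.6758  QALY 1.9807  cost $72448.34 (discounted)
res$gc
#> <cea_outcomes> LY 2.5764  QALY 1.9098  cost $2432.80 (discounted)
res$inc
#> <incremental> dLY 0.0994  dQALY 0.0709  dCost $70015.54
#>   ICER $987164.98/QALY  ($704308.34/LY)
#>   NMB at WTP $38,223: $-67304.54 (not cost-effective)
```

The combination arm gains about 0.1 discounted life years (0.07 QALYs) at
roughly $70,000 extra cost — almost entirely nivolumab acquisition — so its
ICER sits far above the WTP threshold and the net monetary benefit is
deeply negative. The sensitivity layer quantifies how robust that verdict
is:

```r
owsa(model)[1:2, c("param", "low_icer", "high_icer")]
#>                      param low_icer high_icer
#> 1 cost_nivolumab_per_100mg 791372.5 1182957.2
#> 2               utility_pd 1216723.0  830479.2

ps <- psa(model, n = 5000, seed = 1)
prob_cost_effective(ps, 38223)
#> [1] 0

price_threshold(model)$reduction     # price cut needed to reach the WTP
#> [1] 0.9693336
```

The nivolumab unit price is the top tornado parameter, no PSA draw is
cost-effective at the threshold, and only a very large price reduction
would change the decision. A config-driven end-to-end run (synthetic curve
emulation → reconstruction → fitting → model → all analyses, with CSV/JSON
artifacts and a manifest) is available as
`run_cea(system.file("extdata", "base_config.yaml", package = "ucmarkov"), out_dir = "out")`.

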
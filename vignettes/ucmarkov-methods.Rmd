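---
title: "Methods: a Markov cost-effectiveness model for first-line nivolumab plus gemcitabine-cisplatin in advanced urothelial carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model for first-line nivolumab plus gemcitabine-cisplatin in advanced urothelial carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucmarkov)
```

## The decision problem

CheckMate 901 showed that adding nivolumab to first-line
gemcitabine–cisplatin extends overall survival (median 21.7 vs 18.9 months)
and progression-free survival (median 7.9 vs 7.6 months) in advanced
urothelial carcinoma. Whether that benefit is worth its price to a Chinese
payer is a separate question: this package answers it with a
three-state Markov cohort model (progression-free, progressed, dead),
weekly cycles over a 10-year horizon, 5% annual discounting, and a
willingness-to-pay (WTP) threshold of $38,223 per QALY (three times 2022
per-capita GDP).

A cohort model was chosen over a partitioned-survival model so that
background mortality and post-progression death dynamics are explicit
transition probabilities rather than implicit curve areas; the construction
below nevertheless keeps the modelled all-cause survival consistent with
the fitted OS curve, which is the main attraction of partitioned-survival
analysis.

## From published curves to transition matrices

**Pseudo-IPD reconstruction.** Published KM figures are consumed as
digitized `(time, survival)` coordinates plus the numbers-at-risk table.
`reconstruct_ipd()` re-derives individual event and censoring times by
interval accounting: within each risk-table interval a candidate number of
censorings is spread uniformly, events at each read point follow from the
published survival drop, and the candidate is adjusted until the implied
at-risk count at the next table time matches exactly. Two conventions
matter and are fixed here: intervals are *left-open* (a drop read exactly
at a table time is charged to the preceding interval, because that table
entry already excludes those events), and at event/censoring ties the event
comes first. The reconstruction uses only the risk table by default; a
published total-events count, when available, rescales the final interval.
The test-suite asserts a round-trip contract on emulated noise-free curves
(monthly reads, 3-month risk grid, 300 patients, 20 seeds): the KM estimate
of the reconstructed data matches every read-off survival value within 0.02
absolute.

**Parametric extrapolation.** Five families — exponential, Weibull,
lognormal, log-logistic, Gompertz — are fitted to the reconstructed data by
right-censored maximum likelihood (via `flexsurv`) and ranked by AIC
(`2k − 2 logL`; ties broken by fewer parameters, then by the fixed family
order). The Gompertz shape is constrained non-negative so that every
candidate survival function actually reaches zero; when the unconstrained
optimum is negative the model is refit on log-parameters from several
moment-style starts. Parameterizations are documented in
`?parametric_families`; the internal time unit is months everywhere, with
the week conversion (1 month = 365.25/84 weeks) applied only in the
transition engine, to avoid unit drift.

**Transition probabilities.** For a fitted curve S the per-cycle event
probability is `tp(t, u) = 1 − S(t)/S(t−u)`, clipped to [0, 1]. The source
analysis leaves two composition questions open; the package's choices are:

* *Background mortality enters as a floor*: the death probability each
  cycle is `max(trial OS hazard, life-table hazard)` at the attained age.
  A floor (rather than an additive combination) prevents extrapolated trial
  hazards from dipping below general-population mortality without
  double-counting deaths already captured by the trial curve.
* *PFS→Death vs PD→Death split*: the OS-derived death probability applies
  to both alive states, and the PD death probability is back-solved each
  cycle from the current occupancy so that total modelled survival tracks
  the per-cycle product of survival probabilities — i.e. the trace
  reproduces the fitted OS curve (verified to 0.01 absolute in the tests).
  Where extrapolated PFS exceeds OS the PFS curve is clipped to OS, with a
  warning counting the affected grid points.

## Costs and utilities

All amounts are US dollars. Unit costs and their sensitivity ranges:
nivolumab $1249.072 per 100 mg vial (range 999.2576–1498.886), gemcitabine
$5.596 per 0.2 g, cisplatin $1.059 per 10 mg, administration $41 per
infusion visit, terminal care $278.21, and management costs for four
grade ≥ 3 adverse events (anemia $500.78, neutropenia $434.57, decreased
neutrophil count $534.40, decreased white-cell count $622.5231). Utilities
are 0.80 (PFS) and 0.71 (PD). CNY-denominated user inputs convert at the
fixed $1 = ¥7.1470.

Dosing follows the trial: six 3-week combination blocks (nivolumab 360 mg;
gemcitabine 1,000 mg/m² days 1 and 8; cisplatin 70 mg/m² day 1), then
maintenance nivolumab 480 mg every 4 weeks until progression or 2 years;
the control arm receives the chemotherapy blocks alone. Decisions taken
where the source is silent or ambiguous:

* **Body surface area**: Du Bois (`0.007184 · cm^0.725 · kg^0.425`), the
  formula most common in Chinese costing practice; 65 kg and 1.65 m give
  1.72 m². Configurable.
* **Vial wastage**: whole-vial rounding by default (`ceiling(dose/vial)`),
  with a linear option for sensitivity; switching to linear can only lower
  costs (a tested invariant).
* **Administration fee**: read as *per infusion visit*; a combination-arm
  day-1 visit carries two units (immunotherapy + chemotherapy), all other
  visits one.
* **Second-line treatment on progression**: both arms receive a six-block
  gemcitabine–cisplatin course. A memoryless three-state cohort cannot
  schedule a course by time-since-progression without tunnel states, so the
  full course cost attaches as a one-time event cost on each new entry to
  PD. This slightly overstates cost for patients who die mid-course; the
  one-way analysis shows second-line cost has little leverage on the ICER,
  so the simplification is immaterial to the decision.
* **Adverse-event incidences are not published in the source cost table.**
  The shipped profile (anemia 0.22, neutropenia 0.30, decreased neutrophil
  count 0.25, decreased white-cell count 0.15) is a placeholder in the
  range reported for gemcitabine–cisplatin regimens, identical in both arms
  so the one-time cycle-0 AE cost nearly cancels in increments. Replace it
  with trial safety data for any substantive use.
* **Terminal care** applies to all deaths, not only disease deaths.

## Accrual conventions

State membership is valued at cycle midpoints (trapezoidal half-cycle
correction), and each cycle's discount factor is `1.05^(−t_mid)` with time
in exact years of 365.25 days. Event costs — terminal care per new death
and the second-line course per new PD entry — attach to the increment and
are discounted at the cycle end by default; whether the source applied
half-cycle correction to event costs is unstated, so a switch
(`half_cycle_event_costs`) exposes both conventions. The trace is kept at
full precision for all 522 cycles. An individual-level microsimulation
(`microsim_oracle()`) with identical accrual semantics serves as a
validation oracle: at 200,000 paths it agrees with the cohort trace within
three Monte Carlo standard errors on LYs, QALYs and cost.

## Sensitivity analyses

* **One-way (tornado)**: each parameter in turn at its published range
  bounds (±20% of base is the fallback for parameters without a published
  range; the `range_source` column records which rule applied), all others
  at base; parameters ranked by absolute ICER spread. Dominance cases are
  recorded as signed infinite sentinels with their labels, not dropped.
* **Probabilistic**: 5,000 joint draws — Gamma for costs, Beta for
  utilities — built by method of moments with `mean = base` and
  `sd = (high − low)/3.92`, i.e. the published range is read as a 95% CI
  (the divisor is configurable). Survival parameters are *not* varied, as
  the source's distribution table lists only costs and utilities; a failed
  draw is logged and redrawn so the draw count is exact, and the whole PSA
  is reproducible by seed. The CEAC reports, per WTP value, the fraction of
  draws with positive incremental net monetary benefit.
* **Price threshold**: bisection on the nivolumab unit-price multiplier
  (cost is linear in the price and the effect delta is price-invariant, so
  the root is unique) to within $1/QALY of the target, or a 1e-9 multiplier
  bracket. The tests check it against the closed-form solution of the
  linear model.

## The synthetic-data generator

The raw trial data are not public, so the package ships generators
calibrated to the printed summaries. For each arm/endpoint the family
follows the source's AIC selection (log-logistic for OS in both arms and
control-arm PFS; lognormal for combination-arm PFS); the median parameter
is set exactly (log-logistic median = scale; lognormal median =
`exp(meanlog)`); and the shape is chosen so the sampling uncertainty of a
KM median estimated from `n_ref = 300` patients matches the printed 95% CI
width, using the asymptotic identity `CI width = 1.96/(f(m)·sqrt(n))` for
the density f at the median. This closed form is the deterministic limit of
calibrating by Monte Carlo KM confidence intervals, and the test-suite
verifies it with exactly that oracle (simulated-median CI width within
±30% of the printed width). The source does not state arm sizes or the
cohort starting age; `n_ref = 300` (a typical phase-III arm) and age 65 are
documented defaults, not asserted trial values.

Simulated cohorts draw event times by inverse-CDF; censoring is uniform on
`[0, max_follow_up]` for a configurable fraction (default 10%) plus
administrative censoring at the follow-up limit (default 36 months, a
trial-length window) — the source says nothing about censoring structure.
Digitization is emulated by reading the exact KM step function on a grid
and adding truncated Gaussian jitter of 0.002 survival units (plot-reading
error is small but not zero), preserving monotonicity. The life table is a
synthetic Gompertz–Makeham construction,
`q(age) = 1 − exp(−(a + b·e^(c·age)))` with defaults (a = 5e-4, b = 5e-5,
c = 0.09) giving q(65) ≈ 0.018, standing in for census rates; real census
data can be supplied as a CSV with the same schema.

What the generator does *not* emulate: treatment crossover, non-proportional
digitization error (real plot-reading error correlates along the curve),
informative censoring, and covariate heterogeneity. Tests passing on
synthetic data therefore demonstrate that the pipeline's machinery is
correct and internally consistent — not that the shipped numbers reproduce
the source analysis bit-for-bit, which would require the fitted survival
parameters published only in its supplement. For the same reason the
package's base-case ICER is checked as a property (positive QALY gain,
ICER far above twice the WTP, zero PSA acceptance probability, nivolumab
price as the dominant tornado parameter) rather than as an equality.

## Numerical choices

* 522 cycles = `round(10 × 365.25/7)`; week↔month factor fixed at
  365.25/84.
* Transition rows are renormalized only through the explicit
  `1 − max(x, d)` stay-probability; row sums are asserted to 1e-12.
* A depleted survival curve (`S(t−u) = 0`) yields a transition probability
  of 1 with a warning; ages beyond the life table carry its last row.
* Gompertz medians use a bracketed root of `S(t) = 1/2` to 1e-8 months;
  other medians are closed-form.
* AIC ties: fewer parameters first, then the fixed family order.
* Beta moment inversion fails loudly (naming the parameter) when the
  implied variance is infeasible for the mean.

Problem sizes in the shipped test-suite were chosen to keep the full run
around a minute while leaving comfortable statistical margins: 50,000
subjects for generator-calibration checks, 200,000 microsimulation paths,
50 replicates for the AIC model-recovery study, 20 seeds for the
reconstruction round-trip, and the full 5,000 draws for the PSA.

## Known limitations

* The three-state structure has no tunnel states, so anything indexed by
  time-since-progression (second-line duration, late AE costs) must be
  approximated by entry-triggered costs.
* Utilities come from external sources, not trial EQ-5D data; the PD
  utility's wide range (0.57–0.85) makes it the second-largest tornado
  parameter.
* PSA uncertainty excludes survival-model parameters, mirroring the
  source's distribution table; the decision verdict here is insensitive to
  that choice (the cost gap dwarfs plausible effect variation), but the
  CEAC's spread understates total uncertainty.
* Extrapolation beyond 3 years of follow-up is structural: different
  heavy-tailed families fitting the observed window equally well diverge in
  the tail, and the AIC cannot adjudicate beyond the data.
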
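# Synthetic trial-data generators calibrated to the CheckMate 901 summary
# statistics, plus a Gompertz-Makeham life table.  These stand in for the raw
# trial data so the whole pipeline is testable offline.

#' Trial calibration summary for one arm/endpoint
#'
#' @param arm `"nivo_combo"` or `"gem_cis"`.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param median_months Printed median survival, months.
#' @param ci_low_months,ci_high_months Printed 95% CI bounds of the median.
#' @param family Generating family, `"loglogistic"` or `"lognormal"` (the two
#'   shapes the AIC selection favoured for these endpoints).
#' @return A `trial_calibration` object.
#' @export
trial_calibration <- function(arm, endpoint, median_months,
                              ci_low_months, ci_high_months, family) {
  arm <- match.arg(arm, c("nivo_combo", "gem_cis"))
  endpoint <- match.arg(endpoint, c("OS", "PFS"))
  family <- match.arg(family, c("loglogistic", "lognormal"))
  stopifnot(
    is.finite(median_months), median_months > 0,
    is.finite(ci_low_months), ci_low_months > 0,
    is.finite(ci_high_months), ci_high_months > 0,
    ci_low_months < median_months, median_months < ci_high_months
  )
  structure(
    list(arm = arm, endpoint = endpoint, median_months = median_months,
         ci_low_months = ci_low_months, ci_high_months = ci_high_months,
         family = family),
    class = "trial_calibration"
  )
}

#' Shipped calibrations: CheckMate 901 medians and 95% CIs
#'
#' Median OS 21.7 (18.6-26.4) vs 18.9 (14.7-22.4) months; median PFS
#' 7.9 (7.6-9.5) vs 7.6 (6.1-7.8) months.  Log-logistic shapes for OS (both
#' arms) and control-arm PFS, lognormal for combination-arm PFS.
#'
#' @return Named list of four [trial_calibration()] objects:
#'   `nivo_os`, `gc_os`, `nivo_pfs`, `gc_pfs`.
#' @export
trial_calibrations <- function() {
  list(
    nivo_os  = trial_calibration("nivo_combo", "OS",  21.7, 18.6, 26.4, "loglogistic"),
    gc_os    = trial_calibration("gem_cis",    "OS",  18.9, 14.7, 22.4, "loglogistic"),
    nivo_pfs = trial_calibration("nivo_combo", "PFS",  7.9,  7.6,  9.5, "lognormal"),
    gc_pfs   = trial_calibration("gem_cis",    "PFS",  7.6,  6.1,  7.8, "loglogistic")
  )
}

#' Calibrate a parametric family to a printed median and CI
#'
#' The location/scale parameter is set so the model median equals the printed
#' median exactly (log-logistic median = scale; lognormal median =
#' `exp(meanlog)`).  The shape parameter is chosen so that the sampling
#' uncertainty of a Kaplan-Meier median estimated from `n_ref` patients
#' matches the printed CI width: asymptotically the sample median has
#' standard error `1 / (2 f(m) sqrt(n))`, so a 95% CI width of
#' `1.96 / (f(m) sqrt(n))`, which is solved for the shape through the density
#' at the median (`f(m) = shape/(4 scale)` for the log-logistic,
#' `f(m) = 1/(m sdlog sqrt(2 pi))` for the lognormal).  This is a documented
#' heuristic: the printed CI reflects both sampling noise and censoring, so
#' agreement is only expected to within ~30% (checked by Monte Carlo in the
#' test-suite).
#'
#' @param cal A [trial_calibration()] object.
#' @param n_ref Reference sample size per arm (default 300, a realistic
#'   phase-III arm size; the source text does not state arm sizes).
#' @return A [parametric_model()] carrying the calibration as metadata.
#' @export
calibrate_family <- function(cal, n_ref = 300) {
  stopifnot(inherits(cal, "trial_calibration"), n_ref >= 10)
  m <- cal$median_months
  width <- cal$ci_high_months - cal$ci_low_months
  f_m <- 1.96 / (width * sqrt(n_ref))      # implied density at the median
  params <- switch(cal$family,
    loglogistic = list(shape = 4 * m * f_m, scale = m),
    lognormal   = list(meanlog = log(m), sdlog = 1 / (m * f_m * sqrt(2 * pi))),
    stop("unsupported family '", cal$family,
         "'; supported: loglogistic, lognormal", call. = FALSE)
  )
  parametric_model(cal$family, params, calibration = cal, n_ref = n_ref)
}

#' Simulate right-censored individual patient data
#'
#' Event times are drawn by inverse-CDF from the parametric family.  With
#' probability `censor_rate` a subject gets an independent uniform censoring
#' time on `[0, max_follow_up]`; everyone is additionally administratively
#' censored at `max_follow_up`.
#'
#' @param model A `parametric_model`.
#' @param n Number of subjects.
#' @param censor_rate Probability of carrying a random censoring time,
#'   in `[0, 1)`.
#' @param max_follow_up Administrative censoring time in months (may be `Inf`
#'   only when `censor_rate = 0`).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @return A `data.frame(time, event)` with `event = 1` for events, `0` for
#'   right-censored records; the seed is stored as an attribute.
#' @export
simulate_ipd <- function(model, n, censor_rate = 0, max_follow_up = Inf, seed = 1) {
  stopifnot(n >= 1, censor_rate >= 0, censor_rate < 1)
  if (censor_rate > 0 && !is.finite(max_follow_up)) {
    stop("uniform censoring needs a finite max_follow_up", call. = FALSE)
  }
  set.seed(seed)
  t_event <- rsurv_parametric(model, n = n)
  t_cens <- rep(Inf, n)
  if (censor_rate > 0) {
    has_cens <- stats::runif(n) < censor_rate
    t_cens[has_cens] <- stats::runif(sum(has_cens), 0, max_follow_up)
  }
  t_cens <- pmin(t_cens, max_follow_up)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  out <- data.frame(time = time, event = event)
  attr(out, "seed") <- seed
  out
}

#' Emulate a digitized Kaplan-Meier curve with a numbers-at-risk table
#'
#' Simulates a cohort, computes the exact KM estimate, reads it off at
#' `read_times` (adding small truncated digitization jitter), and tabulates
#' numbers at risk on a regular grid — i.e. produces exactly what a
#' plot-digitization workflow yields from a published figure.
#'
#' @param model A `parametric_model` generator.
#' @param read_times Strictly increasing read-off times (months), first `>= 0`.
#' @param n0 Cohort size behind the curve (default 300).
#' @param risk_interval Spacing of the numbers-at-risk grid, months.
#' @param seed Integer seed.
#' @param jitter_sd Digitization error SD in survival units (default 0.002);
#'   jitter is truncated so the read-off sequence stays non-increasing
#'   in `[0, 1]`.
#' @param censor_rate,max_follow_up Passed to [simulate_ipd()];
#'   `max_follow_up` defaults to the last read time.
#' @return A `digitized_curve` list: `curve` (`time_months`, `survival`),
#'   `risk` (`time_months`, `n_at_risk`), `label`, and `flat_extension`
#'   flagging read times beyond the last observed time (survival carried
#'   forward flat, with a warning).
#' @export
emulate_digitized_curve <- function(model, read_times, n0 = 300,
                                    risk_interval = 3, seed = 1,
                                    jitter_sd = 0.002,
                                    censor_rate = 0,
                                    max_follow_up = max(read_times)) {
  stopifnot(length(read_times) >= 2, all(diff(read_times) > 0), read_times[1] >= 0)
  ipd <- simulate_ipd(model, n = n0, censor_rate = censor_rate,
                      max_follow_up = max_follow_up, seed = seed)
  s <- km_estimate(ipd, read_times)
  flat <- read_times > max(ipd$time)
  if (any(flat)) {
    warning("read times beyond last observed time; survival carried forward flat")
  }
  if (jitter_sd > 0) {
    # jitter after seeding the simulation: still reproducible given seed
    s_j <- s + stats::rnorm(length(s), sd = jitter_sd)
    s_j <- pmin(pmax(s_j, 0), 1)
    if (read_times[1] == 0) s_j[1] <- 1
    s <- cummin(s_j)                     # truncate to monotone non-increase
  }
  risk_times <- seq(0, max(read_times), by = risk_interval)
  n_at_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), integer(1))
  structure(
    list(
      curve = data.frame(time_months = read_times, survival = s),
      risk = data.frame(time_months = risk_times, n_at_risk = n_at_risk),
      label = paste0(model$family, "_n", n0, "_seed", seed),
      flat_extension = any(flat)
    ),
    class = "digitized_curve"
  )
}

#' Synthetic Gompertz-Makeham life table
#'
#' Annual all-cause mortality `q(age) = 1 - exp(-(a + b e^(c age)))`, clipped
#' to `[0, 1]`, for integer ages 0..`max_age`.  Defaults give
#' `q(65)` of about 0.018, in the range of a census-style East-Asian
#' population table.  Real census rates can be supplied instead via
#' [read_life_table()] using the same schema.
#'
#' @param makeham_a Age-independent hazard component (per year).
#' @param gompertz_b Gompertz level (per year).
#' @param gompertz_c Gompertz log-slope (per year of age).
#' @param max_age Last tabulated age.
#' @return `data.frame(age, annual_mortality)`.
#' @export
make_life_table <- function(makeham_a = 5e-4, gompertz_b = 5e-5,
                            gompertz_c = 0.09, max_age = 100) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c >= 0, max_age >= 1)
  age <- 0:max_age
  hazard <- makeham_a + gompertz_b * exp(gompertz_c * age)
  q <- pmin(pmax(1 - exp(-hazard), 0), 1)
  data.frame(age = age, annual_mortality = q)
}

# ---- plain-text IO ---------------------------------------------------------

#' @rdname make_life_table
#' @param life_table,path Table and CSV path (`age,annual_mortality` header).
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname make_life_table
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  stopifnot(all(c("age", "annual_mortality") %in% names(lt)))
  if (any(lt$annual_mortality < 0 | lt$annual_mortality > 1)) {
    stop("annual_mortality outside [0,1] in ", path, call. = FALSE)
  }
  lt[c("age", "annual_mortality")]
}

#' Read/write digitized-curve and risk-table CSV pairs
#'
#' Curve CSV has header `time_months,survival`; the companion risk-table CSV
#' has header `time_months,n_at_risk`.
#'
#' @param dc A `digitized_curve` (as from [emulate_digitized_curve()]).
#' @param curve_path,risk_path CSV paths.
#' @export
write_digitized_curve <- function(dc, curve_path, risk_path) {
  utils::write.csv(dc$curve, curve_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dc$risk, risk_path, row.names = FALSE, quote = FALSE)
  invisible(c(curve = curve_path, risk = risk_path))
}

#' @rdname write_digitized_curve
#' @param label Arm/endpoint tag attached to the read curve.
#' @export
read_digitized_curve <- function(curve_path, risk_path, label = "") {
  curve <- utils::read.csv(curve_path)
  risk <- utils::read.csv(risk_path)
  stopifnot(all(c("time_months", "survival") %in% names(curve)),
            all(c("time_months", "n_at_risk") %in% names(risk)))
  structure(list(curve = curve[c("time_months", "survival")],
                 risk = risk[c("time_months", "n_at_risk")],
                 label = label, flat_extension = FALSE),
            class = "digitized_curve")
}
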
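test_that("calibration hits the printed medians exactly", {
  cals <- trial_calibrations()
  expect_equal(calibrate_family(cals$nivo_os)$params$scale, 21.7)
  expect_equal(calibrate_family(cals$gc_os)$params$scale, 18.9)
  expect_equal(calibrate_family(cals$nivo_pfs)$params$meanlog, log(7.9))
  expect_equal(calibrate_family(cals$gc_pfs)$params$scale, 7.6)
  for (cal in cals) {
    expect_equal(median_survival(calibrate_family(cal)), cal$median_months)
  }
})

test_that("unsupported calibration family is rejected with the supported set", {
  cal <- trial_calibrations()$nivo_os
  cal$family <- "weibull"
  expect_error(calibrate_family(cal), "loglogistic, lognormal")
})

test_that("calibrated shape reproduces the printed CI width (Monte Carlo oracle)", {
  # sampling distribution of the KM median of n_ref uncensored subjects:
  # 3.92 * sd over replicates estimates the 95% CI width the shape was
  # calibrated to
  cal <- trial_calibrations()$gc_os
  gen <- calibrate_family(cal, n_ref = 300)
  set.seed(99)
  meds <- replicate(2000, {
    stats::median(flexsurv::rllogis(300, shape = gen$params$shape,
                                    scale = gen$params$scale))
  })
  width_mc <- 3.92 * stats::sd(meds)
  width_printed <- cal$ci_high_months - cal$ci_low_months
  expect_gt(width_mc / width_printed, 0.7)
  expect_lt(width_mc / width_printed, 1.3)
})

test_that("simulated IPD is seed-reproducible and matches closed-form moments", {
  gen <- parametric_model("loglogistic", list(shape = 2, scale = 10))
  a <- simulate_ipd(gen, n = 100, censor_rate = 0.3, max_follow_up = 24, seed = 7)
  b <- simulate_ipd(gen, n = 100, censor_rate = 0.3, max_follow_up = 24, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$time > 0))
  expect_true(all(a$event %in% 0:1))

  # exponential embedded as Weibull shape 1: mean = 1/rate = 10 months
  exp_as_weib <- parametric_model("weibull", list(shape = 1, scale = 10))
  big <- simulate_ipd(exp_as_weib, n = 50000, seed = 21)
  expect_lt(abs(mean(big$time) - 10) / 10, 0.02)

  # log-logistic median = scale
  ll <- simulate_ipd(parametric_model("loglogistic", list(shape = 1.26, scale = 21.7)),
                     n = 50000, seed = 22)
  expect_lt(abs(stats::median(ll$time) - 21.7) / 21.7, 0.015)
})

test_that("noise-free curve read at event times equals the KM step function", {
  gen <- calibrate_family(trial_calibrations()$nivo_os)
  ipd <- simulate_ipd(gen, n = 50, censor_rate = 0, max_follow_up = Inf, seed = 5)
  rt <- c(0, sort(ipd$time))
  dc <- emulate_digitized_curve(gen, read_times = rt, n0 = 50, risk_interval = 12,
                                seed = 5, jitter_sd = 0, censor_rate = 0,
                                max_follow_up = Inf)
  expect_equal(dc$curve$survival, km_estimate(ipd, rt))
})

test_that("emulated curves are monotone and flag flat extension", {
  gen <- calibrate_family(trial_calibrations()$gc_pfs)
  for (s in 1:5) {
    dc <- emulate_digitized_curve(gen, read_times = seq(0, 30, 1), n0 = 120,
                                  seed = s, censor_rate = 0.1)
    expect_true(all(diff(dc$curve$survival) <= 0))
    expect_true(all(dc$curve$survival >= 0 & dc$curve$survival <= 1))
    expect_true(all(diff(dc$risk$n_at_risk) <= 0))
  }
  expect_warning(
    dc <- emulate_digitized_curve(gen, read_times = c(0, 200, 300), n0 = 50,
                                  seed = 1, max_follow_up = 60),
    "carried forward flat"
  )
  expect_true(dc$flat_extension)
})

test_that("emulated combination-arm OS median lands in the printed CI", {
  gen <- calibrate_family(trial_calibrations()$nivo_os)
  dc <- emulate_digitized_curve(gen, read_times = seq(0, 60, 1), n0 = 300,
                                seed = 1, censor_rate = 0, max_follow_up = 60)
  med <- min(dc$curve$time_months[dc$curve$survival <= 0.5])
  expect_gte(med, 18.6)
  expect_lte(med, 26.4)
})

test_that("life table has null-hazard, monotone and ordered mortality", {
  null_lt <- make_life_table(0, 0, 0.09)
  expect_true(all(null_lt$annual_mortality == 0))
  lt <- make_life_table()
  expect_true(all(diff(lt$annual_mortality) >= 0))
  q <- function(a) lt$annual_mortality[lt$age == a]
  expect_gt(q(100), q(65))
  expect_gt(q(65), q(40))
  expect_gt(q(65), 0.01)
  expect_lt(q(65), 0.02)
  expect_true(all(lt$annual_mortality >= 0 & lt$annual_mortality <= 1))
  expect_equal(lt$age, 0:100)
})

test_that("life-table and digitized-curve CSV round-trips preserve values", {
  td <- withr::local_tempdir()
  lt <- make_life_table()
  p <- file.path(td, "lt.csv")
  write_life_table(lt, p)
  expect_equal(read_life_table(p), lt)

  gen <- calibrate_family(trial_calibrations()$nivo_pfs)
  dc <- emulate_digitized_curve(gen, read_times = seq(0, 24, 1), n0 = 80, seed = 2)
  cp <- file.path(td, "curve.csv"); rp <- file.path(td, "risk.csv")
  write_digitized_curve(dc, cp, rp)
  back <- read_digitized_curve(cp, rp, label = dc$label)
  expect_equal(back$curve$survival, dc$curve$survival, tolerance = 1e-12)
  expect_equal(back$risk$n_at_risk, dc$risk$n_at_risk)
})
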
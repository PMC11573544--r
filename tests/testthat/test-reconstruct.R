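make_curve_and_risk <- function(ipd, read_times, risk_times) {
  list(
    curve = data.frame(time_months = read_times,
                       survival = km_estimate(ipd, read_times)),
    risk = data.frame(time_months = risk_times,
                      n_at_risk = vapply(risk_times,
                                         function(tt) sum(ipd$time >= tt),
                                         integer(1)))
  )
}

test_that("product-limit estimator matches textbook and closed-form values", {
  ipd <- data.frame(time = c(1, 2, 3), event = c(1L, 1L, 1L))
  expect_equal(km_estimate(ipd, c(0.5, 1, 2, 3, 10)),
               c(1, 2 / 3, 1 / 3, 0, 0))
  all_cens <- data.frame(time = c(1, 5, 9), event = 0L)
  expect_equal(km_estimate(all_cens, c(0, 2, 20)), c(1, 1, 1))
  expect_true(is.na(km_median(all_cens)))

  set.seed(31)
  big <- data.frame(time = stats::rexp(10000, rate = 0.1), event = 1L)
  med <- log(2) / 0.1
  expect_lt(abs(km_estimate(big, med) - exp(-0.1 * med)), 0.01)
})

test_that("reconstruction is lossless when all information is present", {
  gen <- calibrate_family(trial_calibrations()$nivo_os)
  ipd <- simulate_ipd(gen, n = 50, censor_rate = 0, max_follow_up = Inf, seed = 7)
  tt <- sort(ipd$time)
  cr <- make_curve_and_risk(ipd, c(0, tt), c(0, tt))
  rec <- reconstruct_ipd(cr$curve, cr$risk)
  expect_equal(nrow(rec), 50)
  expect_true(all(rec$event == 1))
  expect_equal(sort(rec$time), tt, tolerance = 1e-12)
})

test_that("a flat curve reconstructs to censorings only", {
  curve <- data.frame(time_months = c(0, 3, 6, 9, 12), survival = 1)
  risk <- data.frame(time_months = c(0, 6, 12), n_at_risk = c(20L, 15L, 10L))
  rec <- reconstruct_ipd(curve, risk)
  expect_equal(nrow(rec), 20)
  expect_true(all(rec$event == 0))
  # censorings fall inside the intervals whose at-risk decrement they explain
  expect_equal(sum(rec$time >= 6), 15)
  expect_equal(sum(rec$time >= 12), 10)
})

test_that("sparse read points still recover the survival median", {
  gen <- parametric_model("loglogistic", list(shape = 2, scale = 10))
  ipd <- simulate_ipd(gen, n = 200, censor_rate = 0.2, max_follow_up = 30, seed = 3)
  # a digitizer traces the curve's visible drops, so the 12 read-off points
  # sit where the published curve crosses regular survival levels
  km_level_time <- function(level) {
    s <- km_estimate(ipd, sort(unique(ipd$time)))
    min(sort(unique(ipd$time))[s <= level])
  }
  levels <- c(0.95, 0.85, 0.75, 0.65, 0.55, 0.5, 0.49, 0.48, 0.35, 0.25)
  rt <- unique(c(0, vapply(levels, km_level_time, numeric(1)), 30))
  cr <- make_curve_and_risk(ipd, rt, seq(0, 30, 3))
  rec <- reconstruct_ipd(cr$curve, cr$risk)
  expect_lt(abs(km_median(rec) - km_median(ipd)) / km_median(ipd), 0.05)
})

test_that("reconstruction conserves at-risk counts at every table time", {
  gen <- calibrate_family(trial_calibrations()$gc_os)
  dc <- emulate_digitized_curve(gen, read_times = seq(0, 36, 1), n0 = 150,
                                risk_interval = 3, seed = 13, jitter_sd = 0,
                                censor_rate = 0.15, max_follow_up = 36)
  rec <- reconstruct_ipd(dc)
  expect_equal(nrow(rec), dc$risk$n_at_risk[1])
  at_risk <- vapply(dc$risk$time_months, function(tt) sum(rec$time >= tt),
                    integer(1))
  expect_equal(at_risk, dc$risk$n_at_risk)
})

test_that("redundant read points on the existing step function change nothing", {
  gen <- parametric_model("loglogistic", list(shape = 2, scale = 12))
  ipd <- simulate_ipd(gen, n = 80, censor_rate = 0.1, max_follow_up = 24, seed = 9)
  rt <- seq(0, 24, 2)
  cr <- make_curve_and_risk(ipd, rt, seq(0, 24, 6))
  base <- reconstruct_ipd(cr$curve, cr$risk)

  # extra points half-way between reads, carrying the left read's survival:
  # exactly on the published (right-continuous) step function
  extra_t <- rt[-length(rt)] + 1
  extra <- data.frame(time_months = extra_t,
                      survival = cr$curve$survival[-length(rt)])
  curve2 <- rbind(cr$curve, extra)
  curve2 <- curve2[order(curve2$time_months), ]
  again <- reconstruct_ipd(curve2, cr$risk)
  expect_equal(sort(again$time[again$event == 1]),
               sort(base$time[base$event == 1]))
  expect_equal(nrow(again), nrow(base))
})

test_that("invalid inputs are rejected", {
  curve_bad <- data.frame(time_months = c(0, 1, 2), survival = c(1, 0.7, 0.8))
  risk <- data.frame(time_months = c(0, 2), n_at_risk = c(10L, 5L))
  expect_error(reconstruct_ipd(curve_bad, risk), "non-monotone")
  curve <- data.frame(time_months = c(0, 1, 2), survival = c(1, 0.8, 0.7))
  risk_bad <- data.frame(time_months = c(0, 2), n_at_risk = c(5L, 10L))
  expect_error(reconstruct_ipd(curve, risk_bad), "increase")
})

test_that("pseudo-IPD CSV round-trips", {
  td <- withr::local_tempdir()
  ipd <- data.frame(time = c(1.5, 2, 3.25), event = c(1L, 0L, 1L))
  p <- file.path(td, "ipd.csv")
  write_pseudo_ipd(ipd, p)
  expect_equal(read_pseudo_ipd(p), ipd)
})
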
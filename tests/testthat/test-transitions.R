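test_that("cycle probability matches closed forms", {
  # constant weekly hazard 0.01: p = 1 - exp(-0.01 u), independent of t
  rate_monthly <- 0.01 * WK_PER_MO
  exp_fit <- parametric_model("exponential", list(rate = rate_monthly))
  for (t in c(1, 10, 250)) {
    expect_equal(cycle_probability(exp_fit, t, 1), 1 - exp(-0.01), tolerance = 1e-12)
  }
  expect_equal(cycle_probability(exp_fit, 10, 1), 0.00995, tolerance = 1e-4)

  # direct-evaluation oracle for the log-logistic (scale 94.3 weeks = 21.7 months)
  ll <- parametric_model("loglogistic", list(shape = 2, scale = 21.7))
  S <- function(t_wk) 1 / (1 + ((t_wk / WK_PER_MO) / 21.7)^2)
  expect_equal(cycle_probability(ll, 10, 1), 1 - S(10) / S(9), tolerance = 1e-12)

  # near-zero hazard: no risk accrues over the interval
  quiet <- parametric_model("exponential", list(rate = 1e-14))
  expect_lt(cycle_probability(quiet, 100, 1), 1e-12)
})

test_that("background death probability converts annual to per-cycle", {
  lt <- data.frame(age = 0:100, annual_mortality = 0.012)
  expect_equal(background_death_prob(lt, 65, 1),
               1 - (1 - 0.012)^(7 / DAYS_YR), tolerance = 1e-12)
  expect_equal(background_death_prob(lt, 65, 1), 2.313e-4, tolerance = 1e-3)
  expect_equal(background_death_prob(zero_life_table(), 65, 1), 0)
  lt1 <- data.frame(age = 0:100, annual_mortality = 1)
  expect_equal(background_death_prob(lt1, 50, 1), 1)
  expect_warning(background_death_prob(lt, 150, 1), "beyond life table")
})

test_that("degenerate schedules behave as expected", {
  clock <- model_clock()
  os <- parametric_model("loglogistic", list(shape = 1.5, scale = 20))
  # identical OS and PFS, no background mortality: everyone exits PFS by death
  sch <- build_schedule(os, os, zero_life_table(), clock)
  expect_true(all(sch$p[, 1, 2] == 0))

  # negligible trial hazards, real life table: only background deaths remain
  quiet <- parametric_model("exponential", list(rate = 1e-14))
  lt <- make_life_table()
  sch2 <- build_schedule(quiet, quiet, lt, clock, start_age = 65)
  ages <- 65 + (0:(clock$cycles - 1)) * 7 / DAYS_YR
  expect_equal(sch2$p[, 1, 3], background_death_prob(lt, ages, 1), tolerance = 1e-9)
  expect_true(all(sch2$p[, 1, 2] == 0))
  expect_equal(sch2$p[, 2, 3], sch2$p[, 1, 3], tolerance = 1e-12)
})

test_that("base-case schedules are proper stochastic matrices at all cycles", {
  m <- base_model()
  for (sch in m$schedules) {
    rs <- apply(sch$p, c(1, 2), sum)
    expect_lt(max(abs(rs - 1)), 1e-12)
    expect_true(all(sch$p >= 0 & sch$p <= 1))
    # death absorbing
    expect_true(all(sch$p[, 3, 3] == 1))
    expect_true(all(sch$p[, 3, 1:2] == 0))
  }
})

test_that("cohort survival tracks the fitted OS curve", {
  m <- base_model()
  clock <- m$clock
  t_mo <- (0:clock$cycles) / WK_PER_MO
  for (arm in c("nivo", "gc")) {
    sch <- m$schedules[[arm]]
    trace <- m$traces[[arm]]
    alive <- 1 - trace[, 3]
    # exact against the per-cycle death product
    expect_equal(alive, cumprod(c(1, 1 - sch$d)), tolerance = 1e-12)
    # and within 0.01 of the fitted OS curve (background floor is the only gap)
    fit <- m$fits[[paste0(arm, "_os")]]
    expect_lt(max(abs(alive - surv_parametric(fit, t = t_mo))), 0.01)
    # PFS occupancy never exceeds the (clipped) PFS curve
    s_pfs <- pmin(surv_parametric(m$fits[[paste0(arm, "_pfs")]], t = t_mo),
                  surv_parametric(fit, t = t_mo))
    expect_true(all(trace[, 1] <= s_pfs + 1e-9))
  }
})

test_that("older cohorts accumulate weakly more deaths", {
  os <- parametric_model("loglogistic", list(shape = 1.3, scale = 30))
  pfs <- parametric_model("loglogistic", list(shape = 1.8, scale = 10))
  lt <- make_life_table()
  dead_at_end <- vapply(c(55, 65, 75, 85), function(a) {
    sch <- suppressWarnings(build_schedule(os, pfs, lt, start_age = a))
    propagate_trace(sch)[523, 3]
  }, numeric(1))
  expect_true(all(diff(dead_at_end) >= -1e-12))
})

test_that("schedule exports to long-format CSV", {
  td <- withr::local_tempdir()
  m <- base_model()
  p <- file.path(td, "sched.csv")
  write_schedule(m$schedules$nivo, p)
  x <- utils::read.csv(p)
  expect_equal(names(x), c("cycle", "from", "to", "p"))
  expect_equal(nrow(x), 522 * 9)
  expect_equal(sum(x$p[x$cycle == 1]), 3, tolerance = 1e-12)
})
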
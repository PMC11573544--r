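test_that("survival functions honour their closed-form identities", {
  # log-logistic median identity S(scale) = 1/2 for any shape
  for (b in c(0.5, 1, 2, 5)) {
    expect_equal(surv_parametric("loglogistic", list(shape = b, scale = 21.7), 21.7), 0.5)
  }
  expect_equal(surv_parametric("exponential", list(rate = 0.05), 0), 1)
  expect_equal(surv_parametric("weibull", list(shape = 1, scale = 20), 20), exp(-1))
  # S(0) = 1, monotone non-increasing, bounded on a 10-year grid, all families
  grid <- seq(0, 120, by = 0.5)
  models <- list(
    parametric_model("exponential", list(rate = 0.04)),
    parametric_model("weibull", list(shape = 1.3, scale = 18)),
    parametric_model("lognormal", list(meanlog = 2, sdlog = 0.8)),
    parametric_model("loglogistic", list(shape = 1.5, scale = 20)),
    parametric_model("gompertz", list(shape = 0.05, rate = 0.02))
  )
  for (m in models) {
    s <- surv_parametric(m, t = grid)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("invalid parameters are rejected", {
  expect_error(surv_parametric("weibull", list(shape = -1, scale = 2), 1), "positive")
  expect_error(surv_parametric("gompertz", list(shape = -0.1, rate = 0.1), 1), "shape")
  expect_error(parametric_model("weibull", list(shape = 2)), "scale")
})

test_that("exponential MLE matches the closed form to 1e-6 relative", {
  set.seed(42)
  ipd <- data.frame(time = stats::rexp(5000, 0.1), event = 1L)
  f <- fit_parametric(ipd, "exponential")
  closed <- sum(ipd$event) / sum(ipd$time)
  expect_true(f$converged)
  expect_lt(abs(f$params$rate - closed) / closed, 1e-6)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
})

test_that("log-logistic parameters are recovered within 5% at n = 5000", {
  gen <- parametric_model("loglogistic", list(shape = 3, scale = 21.7))
  ipd <- simulate_ipd(gen, n = 5000, seed = 17)
  f <- fit_parametric(ipd, "loglogistic")
  expect_lt(abs(f$params$scale - 21.7) / 21.7, 0.05)
  expect_lt(abs(f$params$shape - 3) / 3, 0.05)
})

test_that("Weibull fitted to exponential data finds shape near 1", {
  set.seed(8)
  ipd <- data.frame(time = stats::rexp(5000, 0.08), event = 1L)
  f <- fit_parametric(ipd, "weibull")
  expect_lt(abs(f$params$shape - 1), 0.05)
})

test_that("log-likelihood at the MLE beats random admissible parameters", {
  gen <- parametric_model("weibull", list(shape = 1.5, scale = 15))
  ipd <- simulate_ipd(gen, n = 500, censor_rate = 0.2, max_follow_up = 40, seed = 4)
  f <- fit_parametric(ipd, "weibull")
  ll_hat <- loglik_censored(f, ipd = ipd)
  expect_equal(ll_hat, f$loglik, tolerance = 1e-6)
  set.seed(100)
  for (i in 1:100) {
    p <- list(shape = f$params$shape * exp(stats::runif(1, -0.5, 0.5)),
              scale = f$params$scale * exp(stats::runif(1, -0.5, 0.5)))
    expect_lte(loglik_censored("weibull", p, ipd), ll_hat + 1e-8)
  }
})

test_that("degenerate inputs fail loudly", {
  all_cens <- data.frame(time = stats::runif(20, 1, 10), event = 0L)
  expect_error(fit_parametric(all_cens, "weibull"), "no events")
  tiny <- data.frame(time = c(1, 2, 3), event = 1L)
  expect_error(fit_parametric(tiny, "weibull"), "at least 10")
})

test_that("AIC selection keeps the minimum with documented tie-breaks", {
  fake <- function(family, aic, k, converged = TRUE) {
    structure(list(family = family, aic = aic, k = k, converged = converged),
              class = c("parametric_fit", "parametric_model"))
  }
  fits <- list(fake("weibull", 100, 2), fake("exponential", 99, 1))
  expect_equal(select_by_aic(fits)$family, "exponential")
  # equal AIC: fewer parameters win
  fits <- list(fake("weibull", 100, 2), fake("exponential", 100, 1))
  expect_equal(select_by_aic(fits)$family, "exponential")
  # equal AIC and k: fixed family order decides
  fits <- list(fake("loglogistic", 100, 2), fake("weibull", 100, 2))
  expect_equal(select_by_aic(fits)$family, "weibull")
  # single converged fit returned unchanged
  single <- fake("gompertz", 12, 2)
  expect_identical(select_by_aic(list(single, fake("weibull", 1, 2, FALSE))), single)
  expect_error(select_by_aic(list(fake("weibull", 1, 2, FALSE))), "no converged")
})

test_that("median survival: closed forms and the Gompertz numeric root", {
  expect_equal(median_survival(parametric_model("exponential",
                                                list(rate = log(2) / 18.9))), 18.9)
  expect_equal(median_survival(parametric_model("weibull",
                                                list(shape = 2, scale = 10))),
               10 * log(2)^(1 / 2))
  gom <- parametric_model("gompertz", list(shape = 0.05, rate = 0.02))
  med <- median_survival(gom)
  # brute-force grid oracle at 1e-4-month resolution
  grid <- seq(0, 100, by = 1e-4)
  s <- surv_parametric(gom, t = grid)
  med_grid <- grid[which(s <= 0.5)[1]]
  expect_lt(abs(med - med_grid), 1e-3)
})

test_that("fit serializes to JSON with the reported fields", {
  gen <- parametric_model("loglogistic", list(shape = 2, scale = 10))
  ipd <- simulate_ipd(gen, n = 200, seed = 2)
  f <- fit_parametric(ipd, "loglogistic")
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$family, "loglogistic")
  expect_equal(js$n, 200)
  expect_true(js$converged)
  expect_equal(js$aic, f$aic)
})
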
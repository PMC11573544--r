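# Maximum-likelihood fitting of the five extrapolation families to
# right-censored (pseudo-)IPD, with AIC-based selection.

flexsurv_dist <- function(family) {
  switch(family,
    exponential = "exp",
    weibull     = "weibull",
    lognormal   = "lnorm",
    loglogistic = "llogis",
    gompertz    = "gompertz",
    stop("unsupported family '", family, "'", call. = FALSE)
  )
}

#' Right-censored log-likelihood of a parametric model
#'
#' `sum(log f(t))` over events plus `sum(log S(t))` over censored records,
#' using the package's own density/survival primitives (independent of the
#' fitter, so it can audit a fit).
#'
#' @param family Family name or `parametric_model`.
#' @param params Named parameters (ignored for a `parametric_model`).
#' @param ipd `data.frame(time, event)`.
#' @return Log-likelihood in nats.
#' @export
loglik_censored <- function(family, params = NULL, ipd) {
  ev <- ipd$event == 1
  sum(log(dens_parametric(family, params, ipd$time[ev]))) +
    sum(log(surv_parametric(family, params, ipd$time[!ev])))
}

#' Fit one parametric family by maximum likelihood
#'
#' Delegates to [flexsurv::flexsurvreg()]. A Gompertz fit whose unconstrained
#' shape comes out negative (improper survival: `S(t)` plateaus above 0) is
#' refit with the shape constrained positive by direct optimization of the
#' censored log-likelihood on log-transformed parameters from several
#' moment-style starts.
#'
#' @param ipd `data.frame(time, event)`, at least 10 records and 3 events.
#' @param family One of [parametric_families()].
#' @return A `parametric_fit` (also a `parametric_model`): `family`, `params`
#'   (natural scale), `loglik`, `aic` (`2k - 2 loglik`), `n`, `k`,
#'   `converged`.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, parametric_families())
  n_events <- sum(ipd$event == 1)
  if (n_events == 0) stop("no events: cannot fit a survival model to all-censored data", call. = FALSE)
  if (nrow(ipd) < 10 || n_events < 3) {
    stop("need at least 10 records with at least 3 events", call. = FALSE)
  }
  fs <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = flexsurv_dist(family)),
    error = function(e) e
  )
  if (inherits(fs, "error")) {
    return(structure(
      list(family = family, params = NULL, loglik = NA_real_, aic = NA_real_,
           n = nrow(ipd), k = length(family_param_names(family)),
           converged = FALSE, diagnostics = conditionMessage(fs)),
      class = c("parametric_fit", "parametric_model")
    ))
  }
  params <- as.list(fs$res[, "est"])
  names(params) <- rownames(fs$res)
  if (family == "gompertz" && params$shape < 0) {
    refit <- fit_gompertz_constrained(ipd)
    params <- refit$params
    loglik <- refit$loglik
    converged <- refit$converged
  } else {
    loglik <- fs$loglik
    converged <- TRUE
  }
  k <- length(family_param_names(family))
  out <- parametric_model(family, params)
  out$loglik <- loglik
  out$aic <- 2 * k - 2 * loglik
  out$n <- nrow(ipd)
  out$k <- k
  out$converged <- converged
  class(out) <- c("parametric_fit", class(out))
  out
}

# Constrained Gompertz MLE: optimize over (log shape, log rate), several
# deterministic moment-style starts; a shape pinned near zero degenerates to
# the exponential, which is the proper-survival boundary of the family.
fit_gompertz_constrained <- function(ipd) {
  rate0 <- sum(ipd$event) / sum(ipd$time)
  nll <- function(par) {
    p <- list(shape = exp(par[1]), rate = exp(par[2]))
    ll <- tryCatch(loglik_censored("gompertz", p, ipd), error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- lapply(c(1e-4, 1e-3, 1e-2, 0.05, 0.2), function(a) c(log(a), log(rate0)))
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    return(list(params = list(shape = 1e-8, rate = rate0),
                loglik = loglik_censored("gompertz",
                                         list(shape = 1e-8, rate = rate0), ipd),
                converged = FALSE))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  list(params = list(shape = exp(best$par[1]), rate = exp(best$par[2])),
       loglik = -best$value,
       converged = best$convergence == 0)
}

#' Fit all five families to one dataset
#'
#' @inheritParams fit_parametric
#' @param families Families to fit (default all five).
#' @return Named list of `parametric_fit` objects.
#' @export
fit_all_families <- function(ipd, families = parametric_families()) {
  stats::setNames(lapply(families, function(f) {
    tryCatch(fit_parametric(ipd, f), error = function(e) {
      structure(list(family = f, params = NULL, loglik = NA_real_,
                     aic = NA_real_, n = nrow(ipd),
                     k = length(family_param_names(f)), converged = FALSE,
                     diagnostics = conditionMessage(e)),
                class = c("parametric_fit", "parametric_model"))
    })
  }), families)
}

#' Select the best fit by AIC
#'
#' Minimum AIC among converged fits; ties broken by fewer parameters, then by
#' the fixed family order of [parametric_families()].
#'
#' @param fits List of `parametric_fit` objects.
#' @return The winning `parametric_fit`.
#' @export
select_by_aic <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged fits to select from", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  fam_rank <- match(vapply(fits, `[[`, character(1), "family"), parametric_families())
  fits[[order(aic, k, fam_rank)[1]]]
}

#' Serialize a fit to JSON
#'
#' @param fit A `parametric_fit`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  x <- list(family = fit$family, params = fit$params, loglik = fit$loglik,
            aic = fit$aic, n = fit$n, converged = fit$converged)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else {
    js
  }
}
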
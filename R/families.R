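# Parametric survival families used for extrapolation.
#
# Fixed parameterizations (all times in months):
#   exponential(rate)          S(t) = exp(-rate * t)
#   weibull(shape, scale)      S(t) = exp(-(t/scale)^shape)
#   lognormal(meanlog, sdlog)  S(t) = 1 - Phi((log t - meanlog)/sdlog)
#   loglogistic(shape, scale)  S(t) = 1 / (1 + (t/scale)^shape)
#   gompertz(shape, rate)      S(t) = exp(-(rate/shape) (exp(shape t) - 1)),
#                              shape constrained >= 0 so that S(t) -> 0.

#' Supported parametric survival families
#'
#' @return Character vector of the five family names, in the fixed order used
#'   for AIC tie-breaking.
#' @export
parametric_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")
}

family_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    stop("unsupported family '", family, "'; supported: ",
         paste(parametric_families(), collapse = ", "), call. = FALSE)
  )
}

check_family_params <- function(family, params) {
  wanted <- family_param_names(family)
  if (!all(wanted %in% names(params))) {
    stop("family '", family, "' needs parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  p <- unlist(params[wanted])
  if (any(!is.finite(p))) stop("non-finite parameters for ", family, call. = FALSE)
  positive <- switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = "sdlog",
    loglogistic = c("shape", "scale"),
    gompertz    = "rate"
  )
  if (any(p[positive] <= 0)) {
    stop("parameters ", paste(positive, collapse = ", "), " of ", family,
         " must be strictly positive", call. = FALSE)
  }
  if (family == "gompertz" && p[["shape"]] < 0) {
    stop("gompertz shape must be >= 0 (negative shapes give improper survival)",
         call. = FALSE)
  }
  invisible(p)
}

#' Construct a parametric survival model object
#'
#' Light container shared by the synthetic-data calibrator and the MLE fitter;
#' downstream code (transition engine, medians, simulation) accepts either.
#'
#' @param family One of [parametric_families()].
#' @param params Named list/vector of parameters in the package's fixed
#'   parameterization (times in months).
#' @param ... Extra fields stored on the object (e.g. calibration metadata).
#' @return An object of class `parametric_model`.
#' @export
parametric_model <- function(family, params, ...) {
  family <- match.arg(family, parametric_families())
  check_family_params(family, params)
  structure(
    list(family = family, params = as.list(params)[family_param_names(family)], ...),
    class = "parametric_model"
  )
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model> ", x$family, ": ",
      paste(sprintf("%s=%.6g", names(x$params), unlist(x$params)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

as_family_params <- function(model, family, params) {
  if (!missing(model) && inherits(model, "parametric_model")) {
    list(family = model$family, params = model$params)
  } else {
    list(family = family, params = params)
  }
}

#' Survival function of a parametric family
#'
#' @param family Family name (or a `parametric_model` object, in which case
#'   `params` is ignored).
#' @param params Named parameters.
#' @param t Times in months, `>= 0`.
#' @return `S(t)`, a vector of fractions in `[0, 1]` with `S(0) = 1`.
#' @export
surv_parametric <- function(family, params = NULL, t) {
  if (inherits(family, "parametric_model")) {
    params <- family$params
    family <- family$family
  }
  check_family_params(family, params)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- params
  switch(family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p$shape, scale = p$scale, lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog, lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale, lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate, lower.tail = FALSE)
  )
}

dens_parametric <- function(family, params = NULL, t) {
  if (inherits(family, "parametric_model")) {
    params <- family$params
    family <- family$family
  }
  check_family_params(family, params)
  p <- params
  switch(family,
    exponential = stats::dexp(t, rate = p$rate),
    weibull     = stats::dweibull(t, shape = p$shape, scale = p$scale),
    lognormal   = stats::dlnorm(t, meanlog = p$meanlog, sdlog = p$sdlog),
    loglogistic = flexsurv::dllogis(t, shape = p$shape, scale = p$scale),
    gompertz    = flexsurv::dgompertz(t, shape = p$shape, rate = p$rate)
  )
}

quantile_parametric <- function(family, params = NULL, q) {
  if (inherits(family, "parametric_model")) {
    params <- family$params
    family <- family$family
  }
  check_family_params(family, params)
  p <- params
  switch(family,
    exponential = stats::qexp(q, rate = p$rate),
    weibull     = stats::qweibull(q, shape = p$shape, scale = p$scale),
    lognormal   = stats::qlnorm(q, meanlog = p$meanlog, sdlog = p$sdlog),
    loglogistic = flexsurv::qllogis(q, shape = p$shape, scale = p$scale),
    gompertz    = flexsurv::qgompertz(q, shape = p$shape, rate = p$rate)
  )
}

# Inverse-CDF draw of n event times; caller controls the RNG state.
rsurv_parametric <- function(family, params = NULL, n) {
  u <- stats::runif(n)
  tt <- quantile_parametric(family, params, u)
  if (any(!is.finite(tt))) stop("non-finite event-time draws", call. = FALSE)
  pmax(tt, .Machine$double.xmin)
}

#' Median survival time of a fitted or calibrated model
#'
#' Closed form where available (log-logistic: scale; lognormal: `exp(meanlog)`;
#' exponential: `log(2)/rate`; Weibull: `scale * log(2)^(1/shape)`); a
#' bracketed numeric root of `S(t) = 1/2` (tolerance 1e-8 months) for Gompertz.
#'
#' @param model A `parametric_model` (or fit) object.
#' @return Median survival in months.
#' @export
median_survival <- function(model) {
  stopifnot(inherits(model, "parametric_model"))
  p <- model$params
  switch(model$family,
    exponential = log(2) / p$rate,
    weibull     = p$scale * log(2)^(1 / p$shape),
    lognormal   = exp(p$meanlog),
    loglogistic = p$scale,
    gompertz    = {
      f <- function(t) surv_parametric(model, t = t) - 0.5
      if (f(1e6) > 0) {
        stop("survival never reaches 0.5 within 1e6 months", call. = FALSE)
      }
      stats::uniroot(f, lower = 0, upper = 1e6, tol = 1e-8)$root
    }
  )
}
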
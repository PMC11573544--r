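# One-way (tornado) and probabilistic sensitivity analysis with CEAC.

#' Sensitivity-analysis parameter specifications
#'
#' The eleven varied parameters with their base values, ranges and
#' distribution tags: unit costs and the terminal/administration/AE costs
#' (Gamma), and the two state utilities (Beta).  Ranges are the published
#' ones where stated; parameters without a published range use +/-20% of the
#' base value (the `range_source` column records which rule applied).
#'
#' @return `data.frame(name, base, low, high, dist, role, range_source)`.
#' @export
param_specs <- function() {
  data.frame(
    name = c("cost_nivolumab_per_100mg", "cost_gemcitabine_per_200mg",
             "cost_cisplatin_per_10mg", "cost_administration",
             "cost_terminal_care", "cost_ae_anemia", "cost_ae_neutropenia",
             "cost_ae_neutrophil_count", "cost_ae_wbc_count",
             "utility_pfs", "utility_pd"),
    base = c(1249.072, 5.596, 1.059, 41, 278.21,
             500.78, 434.57, 534.4, 622.5231, 0.8, 0.71),
    low = c(999.2576, 4.4768, 0.8472, 30.75, 222.57,
            445.76, 0, 427.52, 498.02, 0.77, 0.57),
    high = c(1498.886, 6.7152, 1.2708, 51.25, 333.85,
             545.54, 1290.65, 641.28, 747.03, 0.82, 0.85),
    dist = c(rep("gamma", 9), "beta", "beta"),
    role = c(rep("cost", 9), "utility", "utility"),
    range_source = rep("published", 11)
  )
}

# Map a spec name to a modified (econ, utilities) pair.
apply_param <- function(econ, utilities, name, value) {
  switch(name,
    cost_nivolumab_per_100mg   = econ$drugs$nivolumab$price <- value,
    cost_gemcitabine_per_200mg = econ$drugs$gemcitabine$price <- value,
    cost_cisplatin_per_10mg    = econ$drugs$cisplatin$price <- value,
    cost_administration        = econ$administration <- value,
    cost_terminal_care         = econ$terminal_care <- value,
    cost_ae_anemia             = econ$ae_cost[["anemia"]] <- value,
    cost_ae_neutropenia        = econ$ae_cost[["neutropenia"]] <- value,
    cost_ae_neutrophil_count   = econ$ae_cost[["neutrophil_count"]] <- value,
    cost_ae_wbc_count          = econ$ae_cost[["wbc_count"]] <- value,
    utility_pfs                = utilities$u_pfs <- value,
    utility_pd                 = utilities$u_pd <- value,
    stop("unknown parameter '", name, "'", call. = FALSE)
  )
  list(econ = econ, utilities = utilities)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-evaluates the model with each parameter at its low and at its high
#' bound, all others at base, and ranks parameters by the absolute ICER
#' spread.  A bound that produces a dominance case is recorded as a signed
#' infinite sentinel with its label rather than dropped.
#'
#' @param model A [build_cea_model()] object.
#' @param specs Parameter table as [param_specs()].
#' @return `data.frame(param, low_icer, high_icer, spread, low_label,
#'   high_label)` sorted by descending spread.
#' @export
owsa <- function(model, specs = param_specs()) {
  eval_at <- function(name, value) {
    mod <- apply_param(model$econ, model$utilities, name, value)
    res <- evaluate_model(model, econ = mod$econ, utilities = mod$utilities)
    icer <- res$inc$icer_per_qaly
    if (is.na(icer)) {
      icer <- if (identical(res$inc$label, "dominant")) -Inf else Inf
    }
    list(icer = icer, label = res$inc$label)
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    lo <- eval_at(specs$name[i], specs$low[i])
    hi <- eval_at(specs$name[i], specs$high[i])
    data.frame(param = specs$name[i], low_icer = lo$icer, high_icer = hi$icer,
               spread = abs(hi$icer - lo$icer),
               low_label = lo$label %||% "", high_label = hi$label %||% "")
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a sampler for one parameter
#'
#' Method of moments with `mean = base` and `sd = (high - low) / (2 * 1.96)`
#' (the range is read as a 95% CI; the divisor is configurable):
#' Gamma with `shape = mean^2/sd^2`, `rate = mean/sd^2`; Beta by standard
#' moment inversion.  A degenerate range (`sd = 0`) gives a point mass.
#'
#' @param spec One row of [param_specs()] (data.frame or list with `name`,
#'   `base`, `low`, `high`, `dist`).
#' @param ci_divisor Range-to-sd divisor (default `2 * 1.96`).
#' @return `function(n)` drawing `n` values.
#' @export
build_distribution <- function(spec, ci_divisor = 2 * 1.96) {
  m <- spec$base
  s <- (spec$high - spec$low) / ci_divisor
  if (s == 0) return(function(n) rep(m, n))
  switch(tolower(spec$dist),
    gamma = {
      shape <- m^2 / s^2
      rate <- m / s^2
      function(n) stats::rgamma(n, shape = shape, rate = rate)
    },
    beta = {
      v <- s^2
      if (v >= m * (1 - m)) {
        stop("Beta moments infeasible for parameter '", spec$name,
             "': sd too large for mean ", m, call. = FALSE)
      }
      phi <- m * (1 - m) / v - 1
      function(n) stats::rbeta(n, shape1 = m * phi, shape2 = (1 - m) * phi)
    },
    stop("unsupported distribution '", spec$dist, "' for '", spec$name, "'",
         call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' `n` joint Monte Carlo draws (independent across parameters) from the
#' distributions of [build_distribution()]; the model is re-evaluated per
#' draw and the paired incremental cost and QALY recorded.  A draw on which
#' the evaluation fails is logged and redrawn so exactly `n` pairs are
#' returned.  Reproducible by seed.
#'
#' @param model A [build_cea_model()] object.
#' @param n Number of draws (default 5,000).
#' @param seed Integer seed.
#' @param specs Parameter table as [param_specs()].
#' @return A `psa_result`: `draws` (`data.frame(draw, delta_cost,
#'   delta_qaly)`), `n`, `seed`, `redraws`.
#' @export
psa <- function(model, n = 5000, seed = 1, specs = param_specs()) {
  stopifnot(n >= 1)
  set.seed(seed)
  samplers <- lapply(seq_len(nrow(specs)), function(i) build_distribution(specs[i, ]))
  draw_matrix <- function(nn) {
    mm <- vapply(samplers, function(f) f(nn), numeric(nn))
    if (nn == 1) mm <- matrix(mm, nrow = 1)
    mm
  }
  eval_draw <- function(vals) {
    econ <- model$econ; util <- model$utilities
    for (j in seq_len(nrow(specs))) {
      mod <- apply_param(econ, util, specs$name[j], vals[j])
      econ <- mod$econ; util <- mod$utilities
    }
    res <- tryCatch(evaluate_model(model, econ = econ, utilities = util),
                    error = function(e) NULL)
    if (is.null(res)) return(c(NA_real_, NA_real_))
    c(res$inc$delta_cost, res$inc$delta_qaly)
  }
  vals <- draw_matrix(n)
  out <- t(apply(vals, 1, eval_draw))
  redraws <- 0L
  while (anyNA(out)) {
    bad <- which(!stats::complete.cases(out))
    redraws <- redraws + length(bad)
    vals_bad <- draw_matrix(length(bad))
    out[bad, ] <- t(apply(vals_bad, 1, eval_draw))
  }
  if (redraws > 0) message(redraws, " failed PSA draw(s) redrawn")
  structure(
    list(draws = data.frame(draw = seq_len(n), delta_cost = out[, 1],
                            delta_qaly = out[, 2]),
         n = n, seed = seed, redraws = redraws),
    class = "psa_result"
  )
}

#' Probability of cost-effectiveness at one WTP
#'
#' Fraction of PSA draws with positive incremental net monetary benefit.
#'
#' @param psa_result A [psa()] result.
#' @param wtp WTP threshold, $/QALY.
#' @return Fraction in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa_result, wtp) {
  d <- psa_result$draws
  mean(wtp * d$delta_qaly - d$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa_result A [psa()] result.
#' @param wtp_grid WTP grid, $/QALY (default $0-150,000 in $1,000 steps).
#' @return `data.frame(wtp, probability)`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 150000, by = 1000)) {
  stopifnot(nrow(psa_result$draws) > 0)
  data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) prob_cost_effective(psa_result, w),
                         numeric(1))
  )
}
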
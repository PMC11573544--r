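# Incremental analysis and the price-threshold search.

#' Incremental comparison of two strategies
#'
#' Deltas are `a - b`.  An ICER is reported only in the NE quadrant
#' (`delta_qaly > 0` and `delta_cost > 0`); otherwise a dominance label is
#' attached: `"dominant"` (more effect, no extra cost), `"dominated"` /
#' `"dominated (no QALY gain)"`, or `"SW quadrant"` (less costly and less
#' effective, where the ratio is reported but reads as a threshold: the
#' comparator is preferred when the ICER of the forgone benefit exceeds the
#' WTP).  The cost-effectiveness flag is the sign of the incremental net
#' monetary benefit `wtp * delta_qaly - delta_cost`.
#'
#' @param a,b `cea_outcomes` for the intervention and comparator.
#' @param wtp Willingness-to-pay threshold in $/QALY (default $38,223, three
#'   times 2022 Chinese per-capita GDP).
#' @return An `incremental_result` list: `delta_ly`, `delta_qaly`,
#'   `delta_cost`, `icer_per_qaly`, `icer_per_ly`, `nmb`, `wtp`,
#'   `cost_effective`, `label`.
#' @export
incremental <- function(a, b, wtp = 38223) {
  dly <- a$ly - b$ly
  dq <- a$qaly - b$qaly
  dc <- a$cost - b$cost
  eps <- 1e-9
  label <- NULL
  icer_q <- icer_ly <- NA_real_
  if (dq > eps && dc > eps) {
    icer_q <- dc / dq
    if (dly > eps) icer_ly <- dc / dly
  } else if (dq > eps && dc <= eps) {
    label <- "dominant"
  } else if (abs(dq) <= eps && dc > eps) {
    label <- "dominated (no QALY gain)"
  } else if (dq < -eps && dc >= -eps) {
    label <- "dominated"
  } else {
    label <- "SW quadrant"
    icer_q <- dc / dq
    if (abs(dly) > eps) icer_ly <- dc / dly
  }
  nmb <- wtp * dq - dc
  structure(
    list(delta_ly = dly, delta_qaly = dq, delta_cost = dc,
         icer_per_qaly = icer_q, icer_per_ly = icer_ly, nmb = nmb, wtp = wtp,
         cost_effective = nmb > 0, label = label),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental> dLY %.4f  dQALY %.4f  dCost $%.2f\n",
              x$delta_ly, x$delta_qaly, x$delta_cost))
  if (!is.na(x$icer_per_qaly)) {
    cat(sprintf("  ICER $%.2f/QALY", x$icer_per_qaly))
    if (!is.na(x$icer_per_ly)) cat(sprintf("  ($%.2f/LY)", x$icer_per_ly))
    cat("\n")
  }
  if (!is.null(x$label)) cat("  ", x$label, "\n")
  cat(sprintf("  NMB at WTP $%s: $%.2f (%scost-effective)\n",
              format(x$wtp, big.mark = ","), x$nmb,
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Required price reduction to reach a willingness-to-pay threshold
#'
#' Bisection on a unit-price multiplier for one drug (default nivolumab,
#' the component the one-way analysis identifies as decisive) until the
#' base-case ICER is within `tol_icer` of the target WTP, or the multiplier
#' bracket collapses below `tol_mult`.  Deterministic.
#'
#' @param model A [build_cea_model()] object.
#' @param target_wtp Target $/QALY (defaults to the model's WTP).
#' @param drug Drug whose unit price is scaled.
#' @param bracket Multiplier bracket, default `c(0, 1)`; the ICER must be
#'   above the target at the upper end and below it at the lower end.
#' @param tol_icer Absolute ICER tolerance in $/QALY (default 1).
#' @param tol_mult Multiplier-interval tolerance (default 1e-9).
#' @return List: `reduction` (`1 - multiplier`), `multiplier`, `icer`.
#' @export
price_threshold <- function(model, target_wtp = model$wtp, drug = "nivolumab",
                            bracket = c(0, 1), tol_icer = 1, tol_mult = 1e-9) {
  icer_at <- function(m) {
    econ <- model$econ
    econ$drugs[[drug]]$price <- econ$drugs[[drug]]$price * m
    res <- evaluate_model(model, econ = econ)
    res$inc$icer_per_qaly
  }
  icer_hi <- icer_at(bracket[2])
  if (is.na(icer_hi) || icer_hi <= target_wtp) {
    # already at or below the threshold at full price: no reduction needed
    return(list(reduction = 1 - bracket[2], multiplier = bracket[2],
                icer = icer_hi))
  }
  icer_lo <- icer_at(bracket[1])
  if (!is.na(icer_lo) && icer_lo > target_wtp) {
    stop(sprintf(
      "bracket does not straddle the target: ICER %.2f at multiplier %g, %.2f at %g",
      icer_lo, bracket[1], icer_hi, bracket[2]), call. = FALSE)
  }
  lo <- bracket[1]; hi <- bracket[2]
  mid <- (lo + hi) / 2
  repeat {
    mid <- (lo + hi) / 2
    ic <- icer_at(mid)
    below <- is.na(ic) || ic <= target_wtp   # NA: dominance, i.e. below
    if (!below) hi <- mid else lo <- mid
    if ((!is.na(ic) && abs(ic - target_wtp) < tol_icer) || (hi - lo) < tol_mult) break
  }
  list(reduction = 1 - mid, multiplier = mid, icer = icer_at(mid))
}
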
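# Pseudo individual-patient data from digitized Kaplan-Meier coordinates and
# numbers-at-risk tables, via Guyot-type interval accounting: within each
# risk-table interval the number of censorings is solved iteratively so the
# implied at-risk count at the next risk time matches the table, with events
# placed at the read times where the published curve drops.

#' Kaplan-Meier estimate evaluated at given times
#'
#' Product-limit estimator (via [survival::survfit()]) as a right-continuous
#' step function: equals 1 before the first event and carries the last value
#' forward beyond the last observed time.
#'
#' @param ipd `data.frame(time, event)` with `event` 1 = event, 0 = censored.
#' @param eval_times Times (months) at which to read the step function.
#' @return Vector of survival fractions.
#' @export
km_estimate <- function(ipd, eval_times) {
  stopifnot(nrow(ipd) >= 1, all(c("time", "event") %in% names(ipd)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  sf(eval_times)
}

#' Kaplan-Meier median from individual data
#'
#' First time at which the KM step function falls to 0.5 or below
#' (`NA` if it never does).
#'
#' @inheritParams km_estimate
#' @return Median in months, or `NA`.
#' @export
km_median <- function(ipd) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  drop_times <- fit$time[fit$surv <= 0.5 + 1e-12]
  if (length(drop_times) == 0) return(NA_real_)
  min(drop_times)
}

validate_curve_risk <- function(curve, risk) {
  ct <- curve$time_months; cs <- curve$survival
  if (any(diff(ct) <= 0)) stop("curve read times must be strictly increasing", call. = FALSE)
  if (any(diff(cs) > 1e-9)) stop("non-monotone curve: survival increases between read points", call. = FALSE)
  if (cs[1] > 1 + 1e-9) stop("first survival read exceeds 1", call. = FALSE)
  rt <- risk$time_months; rn <- risk$n_at_risk
  if (any(diff(rt) <= 0)) stop("risk-table times must be strictly increasing", call. = FALSE)
  if (any(diff(rn) > 0)) stop("risk counts increase over time", call. = FALSE)
  if (rn[1] < 2) stop("need n_at_risk(0) >= 2", call. = FALSE)
  if (rt[1] > min(ct)) stop("risk table must start at or before the first read time", call. = FALSE)
  invisible(TRUE)
}

#' Reconstruct pseudo-IPD from a digitized KM curve and risk table
#'
#' Within each interval between consecutive risk-table times, a candidate
#' number of censorings is spread uniformly across the interval, events at
#' each read point are recovered from the published survival drop
#' (`d = round(n (1 - S / S_km_prev))`), and the candidate is adjusted until
#' the implied count at risk at the next risk time equals the table entry
#' exactly.  Intervals are left-open: a drop read exactly at a risk-table
#' time is attributed to events up to and including that time, which belong
#' to the preceding interval's at-risk decrement; such events are placed a
#' vanishing offset before the table time (they are not in its at-risk
#' count) unless the count is only consistent with events sitting exactly on
#' it (the information-complete case of a curve read at true event times),
#' in which case they are tied to it.  Beyond the last risk time no interior
#' censoring is assumed; patients still at risk after the last read point
#' are censored there.  If `total_events` is supplied, the final interval's
#' censoring is adjusted so reconstructed events match it.
#'
#' @param curve A `digitized_curve` object, or a `data.frame(time_months,
#'   survival)` when `risk` is given separately.
#' @param risk `data.frame(time_months, n_at_risk)` (ignored when `curve` is a
#'   `digitized_curve`).
#' @param total_events Optional published total number of events.
#' @return `data.frame(time, event)` with exactly `n_at_risk(0)` records.
#' @export
reconstruct_ipd <- function(curve, risk = NULL, total_events = NULL) {
  if (inherits(curve, "digitized_curve")) {
    risk <- curve$risk
    curve <- curve$curve
  }
  stopifnot(!is.null(risk))
  curve <- curve[order(curve$time_months), , drop = FALSE]
  risk <- risk[order(risk$time_months), , drop = FALSE]
  validate_curve_risk(curve, risk)

  # ensure an anchoring (t0, S=1) read point at the first risk time
  t0 <- risk$time_months[1]
  if (curve$time_months[1] > t0) {
    curve <- rbind(data.frame(time_months = t0, survival = 1), curve)
  }
  t <- curve$time_months
  S <- pmin(curve$survival, 1)
  K <- length(t)
  rt <- risk$time_months
  rn <- risk$n_at_risk
  M <- length(rt)

  # left-open interval assignment: a drop read exactly at a risk-table time
  # reflects events up to and including that time, which belong to the
  # preceding interval's at-risk decrement
  interval_of <- findInterval(t, rt, left.open = TRUE)
  interval_of[interval_of == 0] <- 1L        # the (t0, S=1) anchor read
  d <- integer(K)                            # events at read point k
  cens_times <- vector("list", M)            # censoring times per interval
  event_times <- numeric(0)
  km <- numeric(K)                           # running KM product
  km_prev <- 1
  eps_t <- 1e-9                              # boundary event offset, months

  process_interval <- function(ks, n_start, km_prev, ncens, lo, hi,
                               d_override = NULL) {
    # place ncens censorings uniformly on (lo, hi); return accounting
    ct <- if (ncens > 0) lo + seq_len(ncens) * (hi - lo) / (ncens + 1) else numeric(0)
    n <- n_start
    dloc <- integer(length(ks))
    kmloc <- numeric(length(ks))
    closs <- integer(length(ks))
    for (j in seq_along(ks)) {
      k <- ks[j]
      if (!is.null(d_override)) {
        dloc[j] <- d_override[j]
      } else if (n > 0 && km_prev > 0) {
        dloc[j] <- max(0L, min(n, round(n * (1 - S[k] / km_prev))))
      }
      kmloc[j] <- if (n > 0) km_prev * (1 - dloc[j] / n) else km_prev
      km_prev <- kmloc[j]
      upper <- if (j < length(ks)) t[ks[j + 1]] else hi
      closs[j] <- sum(ct >= t[k] & ct < upper) + if (j == 1) sum(ct < t[k]) else 0L
      n <- n - dloc[j] - closs[j]
    }
    list(n_end = n, d = dloc, km = kmloc, cens = ct, km_last = km_prev)
  }

  for (i in seq_len(M)) {
    ks <- which(interval_of == i)
    if (i < M) {
      lo <- rt[i]; hi <- rt[i + 1]; target <- rn[i + 1]
    } else {
      lo <- rt[i]; hi <- max(t[K], rt[i]); target <- NA
    }
    n_start <- if (i == 1) rn[1] else n_next
    if (length(ks) == 0) {
      # no read points inside: difference is all censoring (no drops observed)
      if (i < M) {
        ncens <- n_start - target
        if (ncens > 0) {
          cens_times[[i]] <- lo + seq_len(ncens) * (hi - lo) / (ncens + 1)
        }
        n_next <- target
      } else {
        n_next <- n_start
      }
      next
    }
    if (i < M) {
      ncens <- 0L
      best <- NULL
      seen <- integer(0)
      for (iter in 1:60) {
        res <- process_interval(ks, n_start, km_prev, ncens, lo, hi)
        gap <- res$n_end - target
        if (is.null(best) || abs(gap) < abs(best$gap)) best <- c(res, list(gap = gap, ncens = ncens))
        if (gap == 0) break
        ncens_new <- ncens + gap
        if (ncens_new < 0 || ncens_new %in% seen) break
        seen <- c(seen, ncens)
        ncens <- ncens_new
      }
      ncens <- best$ncens
      res <- process_interval(ks, n_start, km_prev, ncens, lo, hi)
      # interaction of censor placement with event rounding can leave a
      # residual; back off interior censoring first
      while (res$n_end < target && ncens > 0L) {
        ncens <- ncens - 1L
        res <- process_interval(ks, n_start, km_prev, ncens, lo, hi)
      }
      b <- 0L   # events tied exactly to the next risk time (still at risk there)
      if (res$n_end < target) {
        deficit <- target - res$n_end
        last_is_boundary <- abs(t[ks[length(ks)]] - hi) < 1e-9
        if (last_is_boundary) {
          # the table's count at hi includes subjects whose event sits
          # exactly at hi (the information-complete case where the curve
          # was read at true event times): tie that many boundary events
          b <- min(deficit, res$d[length(ks)])
          deficit <- deficit - b
        }
        if (deficit > 0L) {
          # residual rounding overshoot: strip surplus events from the
          # earliest reads (the at-risk table is the authoritative count)
          dd <- res$d
          for (j in seq_along(dd)) {
            take <- min(dd[j], deficit)
            dd[j] <- dd[j] - take
            deficit <- deficit - take
            if (deficit == 0L) break
          }
          res <- process_interval(ks, n_start, km_prev, ncens, lo, hi,
                                  d_override = dd)
        }
      }
      gap <- res$n_end + b - target
      if (gap > 0) {
        lo2 <- max(t[ks])
        res$cens <- c(res$cens, lo2 + seq_len(gap) * (hi - lo2) / (gap + 1))
      }
      n_next <- target - b
    } else {
      res <- process_interval(ks, n_start, km_prev, 0L, lo, hi)
      if (!is.null(total_events)) {
        # adjust final-interval censoring so event totals match
        deficit <- sum(d) + sum(res$d) - total_events
        if (deficit != 0) {
          ncens <- max(0L, -deficit)
          res <- process_interval(ks, n_start, km_prev, ncens, lo, hi)
        }
      }
      b <- 0L
      n_next <- res$n_end
    }
    d[ks] <- res$d
    km[ks] <- res$km
    km_prev <- res$km_last
    cens_times[[i]] <- res$cens
    # place events: at the read times where the drops occur, except that
    # events of a drop read exactly at the next risk time sit just before it
    # (they are not in that time's at-risk count) apart from the b tied ones
    for (j in seq_along(ks)) {
      dj <- res$d[j]
      if (dj == 0L) next
      tk <- t[ks[j]]
      if (j == length(ks) && i < M && abs(tk - hi) < 1e-9) {
        event_times <- c(event_times, rep(hi, b), rep(hi - eps_t, dj - b))
      } else {
        event_times <- c(event_times, rep(tk, dj))
      }
    }
  }

  cens_vec <- unlist(cens_times, use.names = FALSE)
  n_used <- length(event_times) + length(cens_vec)
  n_left <- rn[1] - n_used
  if (n_left < 0) {
    # over-allocation from rounding: trim latest censorings
    cens_vec <- sort(cens_vec)[seq_len(max(0, length(cens_vec) + n_left))]
    n_left <- rn[1] - length(event_times) - length(cens_vec)
  }
  tail_cens <- rep(t[K], max(0, n_left))   # administratively censored at end
  out <- data.frame(
    time = c(event_times, cens_vec, tail_cens),
    event = c(rep(1L, length(event_times)), rep(0L, length(cens_vec) + length(tail_cens)))
  )
  out <- out[order(out$time, -out$event), ]  # event precedes censoring at ties
  rownames(out) <- NULL
  out
}

#' @rdname reconstruct_ipd
#' @param ipd,path Pseudo-IPD and CSV path (`time_months,event` header).
#' @export
write_pseudo_ipd <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname reconstruct_ipd
#' @export
read_pseudo_ipd <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("time_months", "event") %in% names(x)))
  data.frame(time = x$time_months, event = as.integer(x$event))
}
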
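# Per-cycle 3x3 transition matrices over the model horizon, combining the
# fitted OS and PFS curves with background all-cause mortality.
#
# States: 1 = PFS (progression-free), 2 = PD (progressed), 3 = Death.

# fixed month <-> week conversion: 1 month = 365.25/12 days = 365.25/84 weeks
WEEKS_PER_MONTH <- 365.25 / 84
DAYS_PER_YEAR <- 365.25

STATES <- c("PFS", "PD", "Death")

#' Model clock
#'
#' A 1-week cycle over a 10-year horizon by default:
#' `round(10 * 365.25/7) = 522` cycles.
#'
#' @param cycle_length_weeks Cycle length in weeks.
#' @param horizon_years Model horizon in years.
#' @return A `model_clock` list: `cycle_length_weeks`, `horizon_years`,
#'   `cycles`, `weeks_per_year`.
#' @export
model_clock <- function(cycle_length_weeks = 1, horizon_years = 10) {
  stopifnot(cycle_length_weeks > 0, horizon_years > 0)
  structure(
    list(
      cycle_length_weeks = cycle_length_weeks,
      horizon_years = horizon_years,
      cycles = round(horizon_years * DAYS_PER_YEAR / 7 / cycle_length_weeks),
      weeks_per_year = DAYS_PER_YEAR / 7
    ),
    class = "model_clock"
  )
}

#' Per-cycle transition probability from a survival curve
#'
#' The conditional probability of the event during `(t - u, t]`:
#' `1 - S(t)/S(t - u)`, clipped to `[0, 1]`.  Once the curve is numerically
#' depleted (`S(t - u) = 0`) the probability is 1, with a warning.
#'
#' @param fit A `parametric_model`/`parametric_fit` (time unit months).
#' @param t Cycle end time in weeks.
#' @param u Cycle length in weeks.
#' @return Probability in `[0, 1]`.
#' @export
cycle_probability <- function(fit, t, u) {
  stopifnot(u > 0, all(t >= u))
  s_prev <- surv_parametric(fit, t = (t - u) / WEEKS_PER_MONTH)
  s_now <- surv_parametric(fit, t = t / WEEKS_PER_MONTH)
  out <- pmin(pmax(1 - s_now / s_prev, 0), 1)
  depleted <- s_prev <= 0
  if (any(depleted)) {
    warning("survival curve depleted: transition probability set to 1")
    out[depleted] <- 1
  }
  out
}

#' Per-cycle background death probability from a life table
#'
#' Converts the annual probability at the (floored) attained age to the cycle
#' length: `1 - (1 - q)^(u * 7 / 365.25)`.  Ages beyond the table carry the
#' last row (with a warning).
#'
#' @param life_table `data.frame(age, annual_mortality)`.
#' @param age Attained age(s) in years.
#' @param u Cycle length in weeks.
#' @return Probability in `[0, 1]`.
#' @export
background_death_prob <- function(life_table, age, u = 1) {
  stopifnot(u > 0, all(age >= 0))
  idx <- findInterval(floor(age), life_table$age)
  if (any(idx < 1)) stop("age below life-table range", call. = FALSE)
  beyond <- floor(age) > max(life_table$age)
  if (any(beyond)) warning("age beyond life table: carrying last row forward")
  q <- life_table$annual_mortality[pmin(idx, nrow(life_table))]
  1 - (1 - q)^(u * 7 / DAYS_PER_YEAR)
}

#' Build the per-cycle transition schedule for one arm
#'
#' For each cycle the death probability is the OS-derived cycle probability
#' floored by background mortality (`max`); the probability of leaving PFS is
#' the PFS-derived cycle probability (with `S_PFS` clipped to `S_OS` wherever
#' the extrapolated curves cross, with a warning).  PFS->Death gets the death
#' probability, PFS->PD the remainder of the PFS exit.  The PD->Death
#' probability is back-solved each cycle from the current state occupancy so
#' that the modelled all-state survival tracks the per-cycle product of
#' `(1 - death probability)` — keeping the cohort trace consistent with the
#' fitted OS curve — and is floored at the PFS death probability, clipped to
#' `[0, 1]` with a logged diagnostic if the solve leaves that range.
#' Death is absorbing.
#'
#' @param os_fit,pfs_fit Converged `parametric_model`s for OS and PFS
#'   (months).
#' @param life_table `data.frame(age, annual_mortality)`.
#' @param clock A [model_clock()].
#' @param start_age Cohort starting age in years (default 65).
#' @param arm Arm label stored on the schedule.
#' @return A `transition_schedule`: array `p` of dim `c(cycles, 3, 3)`,
#'   per-cycle death probability `d`, clip/solve diagnostics, `clock`,
#'   `start_age`, `arm`.
#' @export
build_schedule <- function(os_fit, pfs_fit, life_table, clock = model_clock(),
                           start_age = 65, arm = "") {
  if (isFALSE(os_fit$converged) || isFALSE(pfs_fit$converged)) {
    stop("both fits must be converged", call. = FALSE)
  }
  N <- clock$cycles
  u <- clock$cycle_length_weeks
  t_wk <- (0:N) * u
  t_mo <- t_wk / WEEKS_PER_MONTH
  s_os <- surv_parametric(os_fit, t = t_mo)
  s_pfs_raw <- surv_parametric(pfs_fit, t = t_mo)
  n_cross <- sum(s_pfs_raw > s_os + 1e-12)
  if (n_cross > 0) {
    warning(sprintf("S_PFS exceeds S_OS at %d of %d grid points; clipped to S_OS",
                    n_cross, N + 1))
  }
  s_pfs <- pmin(s_pfs_raw, s_os)

  age <- start_age + t_wk[-length(t_wk)] * 7 / DAYS_PER_YEAR  # age at cycle start
  d_bg <- suppressWarnings(background_death_prob(life_table, age, u))

  p <- array(0, dim = c(N, 3, 3), dimnames = list(NULL, STATES, STATES))
  d_all <- numeric(N)
  occ <- c(1, 0, 0)
  target_alive <- 1
  n_clipped <- 0L

  for (k in seq_len(N)) {
    d_os <- if (s_os[k] <= 0) 1 else min(max(1 - s_os[k + 1] / s_os[k], 0), 1)
    d <- max(d_os, d_bg[k])
    x <- if (s_pfs[k] <= 0) 1 else min(max(1 - s_pfs[k + 1] / s_pfs[k], 0), 1)

    pfs_death <- d
    pfs_pd <- max(0, x - d)
    pfs_stay <- 1 - max(x, d)

    target_new <- target_alive * (1 - d)
    pq <- occ[1] + occ[2]
    if (occ[2] > 1e-14) {
      d_pd <- 1 - (target_new - occ[1] * (1 - d)) / occ[2]
      if (d_pd < d - 1e-12 || d_pd > 1 + 1e-12) n_clipped <- n_clipped + 1L
      d_pd <- min(max(d_pd, d), 1)
    } else {
      d_pd <- d
    }

    p[k, 1, ] <- c(pfs_stay, pfs_pd, pfs_death)
    p[k, 2, ] <- c(0, 1 - d_pd, d_pd)
    p[k, 3, ] <- c(0, 0, 1)
    d_all[k] <- d

    occ <- as.numeric(occ %*% p[k, , ])
    target_alive <- target_new
  }

  structure(
    list(p = p, d = d_all, clock = clock, start_age = start_age, arm = arm,
         diagnostics = list(pfs_os_crossings = n_cross, d_pd_clipped = n_clipped)),
    class = "transition_schedule"
  )
}

#' Export a transition schedule to long-format CSV
#'
#' Columns `cycle,from,to,p` for audit.
#'
#' @param schedule A `transition_schedule`.
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  N <- dim(schedule$p)[1]
  long <- expand.grid(cycle = seq_len(N), from = STATES, to = STATES,
                      stringsAsFactors = FALSE)
  long$p <- schedule$p[cbind(long$cycle, match(long$from, STATES),
                             match(long$to, STATES))]
  long <- long[order(long$cycle, match(long$from, STATES), match(long$to, STATES)), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
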
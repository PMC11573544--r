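# Shared fixtures.  The calibrated base-case model is deterministic and
# moderately expensive (two 522-cycle schedules), so one cached copy serves
# every test file.

.fixtures <- new.env(parent = emptyenv())

base_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- suppressWarnings(build_cea_model_calibrated())
  }
  .fixtures$model
}

zero_life_table <- function() make_life_table(0, 0, 0.09)

# Schedule applying the same 3x3 matrix (rows = from PFS/PD/Death) each cycle.
constant_schedule <- function(P, clock = model_clock()) {
  N <- clock$cycles
  p <- aperm(array(P, dim = c(3, 3, N)), c(3, 1, 2))
  structure(list(p = p, d = rep(P[1, 3], N), clock = clock, start_age = 65,
                 arm = "synthetic", diagnostics = list()),
            class = "transition_schedule")
}

# All-absorbing progression-free state (no deaths, no progression).
identity_schedule <- function(clock = model_clock()) {
  constant_schedule(diag(3), clock)
}

empty_ledger <- function(clock = model_clock()) {
  N <- clock$cycles
  structure(list(pfs_cost = numeric(N), pd_cost = numeric(N),
                 pd_entry_cost = 0, ae_cost = 0, terminal_cost = 0,
                 clock = clock, arm = "synthetic"),
            class = "strategy_ledger")
}

outcomes_stub <- function(ly, qaly, cost) {
  structure(list(ly = ly, qaly = qaly, cost = cost), class = "cea_outcomes")
}

DAYS_YR <- 365.25
WK_PER_MO <- 365.25 / 84
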
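# Per-cycle cost accrual: drug acquisition (whole-vial wastage by default),
# administration fees, one-time adverse-event costs, second-line treatment on
# progression, and terminal care.  All amounts in US dollars.

#' Economic parameters (unit costs)
#'
#' Base-case unit costs: nivolumab $1249.072 per 100 mg vial, gemcitabine
#' $5.596 per 0.2 g vial, cisplatin $1.059 per 10 mg vial, administration
#' $41 per infusion visit, terminal end-of-life care $278.21, and grade >= 3
#' adverse-event management costs (anemia $500.78, neutropenia $434.57,
#' decreased neutrophil count $534.40, decreased white-cell count $622.5231).
#' CNY-denominated user inputs can be converted at the fixed rate
#' $1 = 7.1470 yuan.
#'
#' @param wastage `"whole_vial"` (default) or `"linear"` dose costing.
#' @return An `econ_params` list.
#' @export
econ_params <- function(wastage = c("whole_vial", "linear")) {
  wastage <- match.arg(wastage)
  structure(
    list(
      drugs = list(
        nivolumab   = list(vial_mg = 100, price = 1249.072),
        gemcitabine = list(vial_mg = 200, price = 5.596),
        cisplatin   = list(vial_mg = 10,  price = 1.059)
      ),
      administration = 41,
      terminal_care = 278.21,
      ae_cost = c(anemia = 500.78, neutropenia = 434.57,
                  neutrophil_count = 534.4, wbc_count = 622.5231),
      cny_per_usd = 7.1470,
      wastage = wastage
    ),
    class = "econ_params"
  )
}

#' Body surface area (Du Bois)
#'
#' `0.007184 * height_cm^0.725 * weight_kg^0.425`.
#'
#' @param weight_kg Body weight, kg (default 65).
#' @param height_m Height, m (default 1.65).
#' @return BSA in square metres.
#' @export
body_surface_area <- function(weight_kg = 65, height_m = 1.65) {
  stopifnot(weight_kg > 0, height_m > 0)
  0.007184 * (height_m * 100)^0.725 * weight_kg^0.425
}

#' Drug acquisition cost for a single administration
#'
#' Whole-vial wastage rounds the dose up to whole purchasable vials
#' (`ceiling(dose/vial) * price`); linear costing charges the exact fraction.
#'
#' @param drug Drug name present in `econ$drugs`.
#' @param dose_mg Administered dose in mg.
#' @param econ An [econ_params()] object.
#' @param wastage Override of the costing policy.
#' @return Cost in US$.
#' @export
drug_cost_per_administration <- function(drug, dose_mg, econ = econ_params(),
                                         wastage = econ$wastage) {
  if (!drug %in% names(econ$drugs)) {
    stop("unknown drug '", drug, "'; known: ",
         paste(names(econ$drugs), collapse = ", "), call. = FALSE)
  }
  stopifnot(dose_mg > 0)
  d <- econ$drugs[[drug]]
  vials <- dose_mg / d$vial_mg
  if (wastage == "whole_vial") vials <- ceiling(vials - 1e-9)
  vials * d$price
}

# ---- regimens --------------------------------------------------------------

# A regimen is an unrolled administration table: one row per drug per
# administration day, mapped onto weekly model cycles.  A 21-day block spans
# 3 weekly cycles: day-1 administrations fall in the block's first week,
# day-8 administrations in its second.  admin_units counts infusion visits
# attributable to the row (co-administered drugs on the same visit carry 0).

regimen_obj <- function(schedule, label) {
  dup <- duplicated(schedule[c("week", "drug")])
  if (any(dup)) stop("overlapping schedule entries for one drug on one day", call. = FALSE)
  structure(list(schedule = schedule, label = label), class = "regimen")
}

#' First-line regimens and the second-line course
#'
#' `regimen_nivo_gc()`: nivolumab 360 mg plus gemcitabine 1,000 mg/m2
#' (days 1 and 8) and cisplatin 70 mg/m2 (day 1), every 3 weeks for a maximum
#' of six blocks; then maintenance nivolumab 480 mg every 4 weeks from week
#' 18 until progression or a maximum of 2 years (no administrations after
#' week 104).  `regimen_gc()`: gemcitabine-cisplatin alone, six 3-week
#' blocks.  `regimen_second_line_gc()`: the post-progression
#' gemcitabine-cisplatin course (default six blocks), used as an
#' entry-triggered cost.
#'
#' Day-1 visits in the combination arm count 2 administration units
#' (immunotherapy infusion + chemotherapy visit); chemotherapy-only day-1 and
#' all day-8 visits count 1.
#'
#' @param blocks Number of 3-week chemotherapy blocks.
#' @param maintenance_through_week Last week in which a maintenance dose may
#'   be given (2-year stopping rule: 104).
#' @return A `regimen` object with columns
#'   `week, drug, dose, unit ("mg"|"mg_per_m2"), admin_units`.
#' @export
regimen_nivo_gc <- function(blocks = 6, maintenance_through_week = 104) {
  b <- seq_len(blocks) - 1
  d1 <- data.frame(
    week = rep(3 * b, each = 3),
    drug = rep(c("nivolumab", "gemcitabine", "cisplatin"), blocks),
    dose = rep(c(360, 1000, 70), blocks),
    unit = rep(c("mg", "mg_per_m2", "mg_per_m2"), blocks),
    admin_units = rep(c(1, 1, 0), blocks)
  )
  d8 <- data.frame(week = 3 * b + 1, drug = "gemcitabine", dose = 1000,
                   unit = "mg_per_m2", admin_units = 1)
  maint_weeks <- seq(3 * blocks, maintenance_through_week, by = 4)
  maint <- data.frame(week = maint_weeks, drug = "nivolumab", dose = 480,
                      unit = "mg", admin_units = 1)
  regimen_obj(rbind(d1, d8, maint), "nivolumab + gemcitabine-cisplatin")
}

#' @rdname regimen_nivo_gc
#' @export
regimen_gc <- function(blocks = 6) {
  b <- seq_len(blocks) - 1
  d1 <- data.frame(
    week = rep(3 * b, each = 2),
    drug = rep(c("gemcitabine", "cisplatin"), blocks),
    dose = rep(c(1000, 70), blocks),
    unit = "mg_per_m2",
    admin_units = rep(c(1, 0), blocks)
  )
  d8 <- data.frame(week = 3 * b + 1, drug = "gemcitabine", dose = 1000,
                   unit = "mg_per_m2", admin_units = 1)
  regimen_obj(rbind(d1, d8), "gemcitabine-cisplatin")
}

#' @rdname regimen_nivo_gc
#' @export
regimen_second_line_gc <- function(blocks = 6) regimen_gc(blocks)

#' Placeholder grade >= 3 adverse-event profile
#'
#' Incidences are NOT published in the source cost table; these are
#' placeholder defaults in the range reported for gemcitabine-cisplatin
#' regimens, identical in both arms (so they largely cancel in incremental
#' results), and should be replaced with trial safety data where available.
#'
#' @return `data.frame(ae, incidence)` matching the names of
#'   `econ_params()$ae_cost`.
#' @export
default_ae_profile <- function() {
  data.frame(
    ae = c("anemia", "neutropenia", "neutrophil_count", "wbc_count"),
    incidence = c(0.22, 0.30, 0.25, 0.15)
  )
}

regimen_row_cost <- function(schedule, econ, bsa, wastage) {
  dose_mg <- ifelse(schedule$unit == "mg_per_m2", schedule$dose * bsa, schedule$dose)
  drug_cost <- mapply(function(drug, dose) {
    drug_cost_per_administration(drug, dose, econ, wastage)
  }, schedule$drug, dose_mg)
  drug_cost + schedule$admin_units * econ$administration
}

#' Build the per-cycle cost ledger for one strategy
#'
#' Maps the first-line administration table onto weekly model cycles
#' (PFS-state costs), prices the second-line gemcitabine-cisplatin course as
#' a one-time cost on entry to PD, sums incidence-weighted adverse-event
#' costs into a one-time cycle-0 cost, and attaches the terminal-care cost
#' per new death.
#'
#' @param regimen First-line `regimen` for the arm.
#' @param econ An [econ_params()] object.
#' @param clock A [model_clock()].
#' @param ae_profile `data.frame(ae, incidence)`.
#' @param second_line Second-line `regimen` (priced as a full course on PD
#'   entry).
#' @param weight_kg,height_m Body metrics for BSA-dosed drugs.
#' @return A `strategy_ledger`: vectors `pfs_cost`, `pd_cost` (length
#'   `clock$cycles`; cycle k covers week k-1), scalars `pd_entry_cost`,
#'   `ae_cost`, `terminal_cost`.
#' @export
build_cost_ledger <- function(regimen, econ = econ_params(),
                              clock = model_clock(),
                              ae_profile = default_ae_profile(),
                              second_line = regimen_second_line_gc(),
                              weight_kg = 65, height_m = 1.65) {
  stopifnot(inherits(regimen, "regimen"), inherits(second_line, "regimen"))
  bsa <- body_surface_area(weight_kg, height_m)
  N <- clock$cycles

  sched <- regimen$schedule
  if (any(duplicated(sched[c("week", "drug")]))) {
    stop("overlapping schedule entries for one drug on one day", call. = FALSE)
  }
  row_cost <- regimen_row_cost(sched, econ, bsa, econ$wastage)
  pfs_cost <- numeric(N)
  cyc <- sched$week + 1                     # cycle k covers week k-1
  keep <- cyc >= 1 & cyc <= N
  agg <- tapply(row_cost[keep], cyc[keep], sum)
  pfs_cost[as.integer(names(agg))] <- as.numeric(agg)

  pd_entry_cost <- sum(regimen_row_cost(second_line$schedule, econ, bsa, econ$wastage))

  idx <- match(ae_profile$ae, names(econ$ae_cost))
  if (any(is.na(idx))) {
    stop("unknown adverse event(s): ",
         paste(ae_profile$ae[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ae_cost <- sum(ae_profile$incidence * econ$ae_cost[idx])

  structure(
    list(pfs_cost = pfs_cost, pd_cost = numeric(N),
         pd_entry_cost = pd_entry_cost, ae_cost = ae_cost,
         terminal_cost = econ$terminal_care, clock = clock,
         arm = regimen$label),
    class = "strategy_ledger"
  )
}

#' Export a ledger's per-cycle state costs to CSV
#'
#' Long format `cycle,state,cost_usd`.
#'
#' @param ledger A `strategy_ledger`.
#' @param path CSV path.
#' @export
write_ledger <- function(ledger, path) {
  N <- length(ledger$pfs_cost)
  out <- rbind(
    data.frame(cycle = seq_len(N), state = "PFS", cost_usd = ledger$pfs_cost),
    data.frame(cycle = seq_len(N), state = "PD", cost_usd = ledger$pd_cost)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
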
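#' Treatment strategy definitions
#'
#' A strategy bundles everything arm-specific: the 12-month outcome
#' proportions its remission/relapse transitions are calibrated to, its
#' adverse-event profile, and its drug / steroid / monitoring cost
#' schedule. Both constructors read every number from the parameter table
#' so that sensitivity analyses that perturb the table propagate
#' automatically.
#'
#' @param pt A `param_table` from [load_parameter_table()].
#' @return A `strategy` object.
#' @name strategies
NULL

.strategy <- function(name, arm, pt) {
  tg <- attr(pt, "outcome_targets")[[arm]]
  structure(list(
    name = name,
    arm = arm,
    targets = c(cr = tg$cr / tg$size, pr = tg$pr / tg$size, relapse = tg$relapse / tg$size),
    target_counts = c(n = tg$size, cr = tg$cr, pr = tg$pr, relapse = tg$relapse)
  ), class = "strategy")
}

#' @rdname strategies
#' @export
#' @examples
#' pt <- load_parameter_table()
#' strategy_rtx(pt)$targets
strategy_rtx <- function(pt) .strategy("RTX", "rtx", pt)

#' @rdname strategies
#' @export
strategy_tac <- function(pt) .strategy("TAC", "tac", pt)

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy %s> 12-month targets: CR %.2f%%, PR %.2f%%, relapse %.2f%%\n",
              x$name, 100 * x$targets["cr"], 100 * x$targets["pr"],
              100 * x$targets["relapse"]))
  invisible(x)
}

#' Adverse-event profile of a strategy
#'
#' Pairs each adverse event's per-course incidence with its per-event
#' treatment cost, both read from the parameter table.
#'
#' @param strategy A `strategy`.
#' @param pt A `param_table`.
#' @return Data frame with columns `ae`, `incidence`, `cost`.
#' @export
ae_profile <- function(strategy, pt) {
  prefix <- paste0("ae_incidence.", strategy$arm, ".")
  rows <- pt[startsWith(pt$name, prefix), , drop = FALSE]
  ae <- sub(prefix, "", rows$name)
  data.frame(ae = ae,
             incidence = rows$mean,
             cost = param_value(pt, paste0("ae_cost.", ae)),
             row.names = NULL)
}

#' Expected adverse-event cost of one treatment course
#'
#' Sum of incidence times per-event cost over the profile; applied as a
#' one-time expected cost at each treatment-course cycle.
#'
#' @param profile Data frame with columns `incidence` and `cost`
#'   (see [ae_profile()]); may be empty.
#' @return Expected cost in yuan.
#' @export
#' @examples
#' pt <- load_parameter_table()
#' expected_ae_cost(ae_profile(strategy_rtx(pt), pt))
expected_ae_cost <- function(profile) {
  if (nrow(profile) == 0L) return(0)
  if (any(profile$incidence < 0 | profile$incidence > 1)) {
    stop("adverse-event incidences must lie in [0, 1]", call. = FALSE)
  }
  if (any(profile$cost < 0)) {
    stop("adverse-event costs must be nonnegative", call. = FALSE)
  }
  sum(profile$incidence * profile$cost)
}

# Methylprednisolone-equivalent dose (mg/day) at a given treatment cycle.
.steroid_mg_per_day <- function(cycle, st) {
  start <- st$tac_steroid_start_mg_per_kg * st$body_weight_kg
  if (cycle < st$tac_steroid_taper_start_cycle) return(start)
  max(start - st$tac_steroid_taper_step_mg *
        (cycle - st$tac_steroid_taper_start_cycle + 1L),
      st$tac_steroid_maintenance_mg)
}

#' Per-cycle strategy-specific cost for the cohort
#'
#' Computes the drug, steroid, monitoring-visit and expected adverse-event
#' cost a strategy charges in a given cycle, weighted by the cohort
#' occupancy at the cycle start. The rituximab arm charges one induction
#' course (4 weekly doses of 375 mg/m2, whole vials) over cycles 1-2 and a
#' second full course at the 6-month evaluation weighted by the fraction
#' of the cohort then in partial remission; the tacrolimus arm charges the
#' published state-dependent 6-month drug costs spread uniformly over the
#' 12 treatment cycles plus the tapering steroid co-medication. Both arms
#' pay evaluation-visit costs at months 1, 3, 6, 9 and 12 and a one-time
#' expected adverse-event cost per treatment course.
#'
#' @param strategy A `strategy`.
#' @param pt A `param_table`.
#' @param cycle Cycle index (1-based).
#' @param occ Length-8 occupancy vector at the cycle start, in
#'   [health_states()] order.
#' @return Cost in yuan accrued by the cohort in this cycle.
#' @export
strategy_cycle_cost <- function(strategy, pt, cycle, occ) {
  .make_cycle_cost(strategy, pt)(cycle, occ)
}

# Precompute every unit cost once and return a fast (cycle, occ) -> cost
# closure; run_cohort and the PSA call this once per trace, not per cycle.
# Occupancy indices: 1 active, 2 cr, 3 pr, 4 relapse.
.make_cycle_cost <- function(strategy, pt) {
  st <- model_settings(pt)
  visit <- sum(param_value(pt, c("cost.urinalysis", "cost.rapid_proteinuria_test",
                                 "cost.quant_proteinuria_test",
                                 "cost.liver_function_test")))
  monitoring <- st$monitoring_cycles
  eac <- expected_ae_cost(ae_profile(strategy, pt))

  if (strategy$arm == "rtx") {
    dose_mg <- st$rtx_dose_mg_per_m2 * st$body_surface_area_m2
    vials <- ceiling(dose_mg / st$rtx_vial_mg)
    induction <- st$rtx_doses_per_induction * vials * param_value(pt, "cost.rtx_vial")
    second_cycle <- st$rtx_second_course_cycle
    function(cycle, occ) {
      cost <- 0
      if (cycle %in% monitoring) cost <- visit * sum(occ[1:4])
      if (cycle <= 2L) cost <- cost + induction / 2
      if (cycle == 1L) cost <- cost + eac
      if (cycle == second_cycle) cost <- cost + occ[3L] * (induction + eac)
      cost
    }
  } else {
    sixmo <- param_value(pt, c("cost.tac_6mo_nr", "cost.tac_6mo_cr",
                               "cost.tac_6mo_pr", "cost.tac_6mo_relapse")) / 6
    tab_cost <- param_value(pt, "cost.methylprednisolone_4mg_tab")
    rx_cycles <- st$tac_treatment_cycles
    steroid <- vapply(seq_len(rx_cycles), function(cy) {
      (.steroid_mg_per_day(cy, st) / 4) * tab_cost * st$cycle_length_days
    }, numeric(1))
    function(cycle, occ) {
      cost <- 0
      if (cycle %in% monitoring) cost <- visit * sum(occ[1:4])
      if (cycle <= rx_cycles) {
        cost <- cost + sum(occ[1:4] * sixmo) + steroid[cycle] * sum(occ[1:4])
      }
      if (cycle == 1L) cost <- cost + eac
      cost
    }
  }
}
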
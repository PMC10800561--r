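#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @return List with `icer` (a finite ratio, or `NA` under dominance) and
#'   `dominance`, one of `"none"`, `"dominant"` (cheaper and more
#'   effective), `"dominated"` (dearer and less effective) or
#'   `"indifferent"` (no QALY difference).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    dom <- if (delta_cost == 0) "indifferent"
           else if (delta_cost < 0) "dominant" else "dominated"
    return(list(icer = NA_real_, dominance = dom))
  }
  if (delta_cost <= 0 && delta_qaly > 0) {
    return(list(icer = NA_real_, dominance = "dominant"))
  }
  if (delta_cost >= 0 && delta_qaly < 0) {
    return(list(icer = NA_real_, dominance = "dominated"))
  }
  list(icer = delta_cost / delta_qaly, dominance = "none")
}

#' Net monetary benefit
#'
#' @param cost Total (discounted) cost.
#' @param qaly Total (discounted) QALYs.
#' @param wtp Willingness-to-pay threshold per QALY.
#' @return `wtp * qaly - cost`.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) wtp * qaly - cost

#' Compare two strategies' cohort traces
#'
#' Computes the yearly cumulative discounted cost/QALY table for both
#' arms, the incremental cost and QALYs at the horizon, the ICER (or a
#' dominance flag when the ratio is not meaningful), per-arm net monetary
#' benefit at the willingness-to-pay threshold, and the resulting
#' decision: the intervention is deemed cost-effective when it dominates
#' or when it buys QALYs at or below the threshold.
#'
#' @param trace_a Intervention `cohort_trace`.
#' @param trace_b Comparator `cohort_trace`.
#' @param wtp Willingness-to-pay threshold per QALY.
#' @return A `cea_result`.
#' @export
#' @examples
#' pt <- load_parameter_table()
#' res <- compare_strategies(run_cohort(strategy_rtx(pt), pt, 2),
#'                           run_cohort(strategy_tac(pt), pt, 2),
#'                           wtp = model_settings(pt)$wtp_per_qaly)
#' res$delta_qaly
compare_strategies <- function(trace_a, trace_b, wtp) {
  if (trace_a$convention$n_cycles != trace_b$convention$n_cycles ||
      trace_a$convention$cycles_per_year != trace_b$convention$cycles_per_year) {
    stop("traces have mismatched horizons or cycle conventions", call. = FALSE)
  }
  ya <- .yearly_cumulative(trace_a)
  yb <- .yearly_cumulative(trace_b)
  n <- trace_a$convention$n_cycles
  cost_a <- trace_a$cum_cost_disc[n]; qaly_a <- trace_a$cum_qaly_disc[n]
  cost_b <- trace_b$cum_cost_disc[n]; qaly_b <- trace_b$cum_qaly_disc[n]
  delta_cost <- cost_a - cost_b
  delta_qaly <- qaly_a - qaly_b
  ic <- icer(delta_cost, delta_qaly)
  nmb_a <- net_monetary_benefit(cost_a, qaly_a, wtp)
  nmb_b <- net_monetary_benefit(cost_b, qaly_b, wtp)
  cost_effective <- ic$dominance == "dominant" ||
    (ic$dominance == "none" && delta_qaly > 0 && ic$icer <= wtp)
  structure(list(
    arm_a = trace_a$strategy, arm_b = trace_b$strategy,
    yearly = data.frame(year = ya$year,
                        cum_cost_a = ya$cum_cost, cum_qaly_a = ya$cum_qaly,
                        cum_cost_b = yb$cum_cost, cum_qaly_b = yb$cum_qaly),
    cost_a = cost_a, qaly_a = qaly_a, cost_b = cost_b, qaly_b = qaly_b,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icer = ic$icer, dominance = ic$dominance,
    nmb_a = nmb_a, nmb_b = nmb_b,
    wtp = wtp, cost_effective = cost_effective),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s over %d year(s)\n", x$arm_a, x$arm_b,
              max(x$yearly$year)))
  cat(sprintf("  %s: cost %.2f, QALY %.4f | %s: cost %.2f, QALY %.4f\n",
              x$arm_a, x$cost_a, x$qaly_a, x$arm_b, x$cost_b, x$qaly_b))
  cat(sprintf("  delta cost %.0f, delta QALY %.4f\n", round(x$delta_cost),
              x$delta_qaly))
  if (x$dominance == "none") {
    cat(sprintf("  ICER %.2f per QALY (WTP %.0f) -> %s\n", x$icer, x$wtp,
                if (x$cost_effective) "cost-effective" else "not cost-effective"))
  } else {
    cat(sprintf("  dominance: %s (WTP %.0f) -> %s\n", x$dominance, x$wtp,
                if (x$cost_effective) "cost-effective" else "not cost-effective"))
  }
  invisible(x)
}

#' Export a CEA result as CSV (yearly table) and JSON (summary)
#'
#' @param result A `cea_result`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisible character vector of files written.
#' @export
export_cea_result <- function(result, csv_path = NULL, json_path = NULL) {
  written <- character()
  if (!is.null(csv_path)) {
    utils::write.csv(result$yearly, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    summary <- result[c("arm_a", "arm_b", "cost_a", "qaly_a", "cost_b",
                        "qaly_b", "delta_cost", "delta_qaly", "icer",
                        "dominance", "nmb_a", "nmb_b", "wtp",
                        "cost_effective")]
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, json_path)
  }
  invisible(written)
}
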
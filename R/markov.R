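#' Cycle and discounting conventions
#'
#' The model year is 12 cycles of 30 days (360 days), so annual rates and
#' the cycle grid align without fractional cycles; a 5-year horizon is 60
#' cycles. Costs and QALYs accrued in cycle `t` are discounted by
#' `(1 + rate)^(-t / cycles_per_year)`.
#'
#' @param horizon_years Model horizon in years.
#' @param cycle_length_days Days per cycle.
#' @param cycles_per_year Cycles per model year.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @return A `cycle_convention` list.
#' @export
cycle_convention <- function(horizon_years = 5, cycle_length_days = 30,
                             cycles_per_year = 12, discount_rate = 0.05) {
  stopifnot(horizon_years >= 1, cycles_per_year >= 1, discount_rate >= 0)
  structure(list(horizon_years = horizon_years,
                 cycle_length_days = cycle_length_days,
                 cycles_per_year = cycles_per_year,
                 discount_rate = discount_rate,
                 n_cycles = cycles_per_year * horizon_years),
            class = "cycle_convention")
}

.conv_from_settings <- function(pt, horizon_years = NULL) {
  st <- model_settings(pt)
  cycle_convention(
    horizon_years = if (is.null(horizon_years)) st$horizon_years else horizon_years,
    cycle_length_days = st$cycle_length_days,
    cycles_per_year = st$cycles_per_year,
    discount_rate = st$discount_rate)
}

#' Per-cycle probability matching a cumulative multi-cycle target
#'
#' Constant-hazard inversion: returns `p` with
#' `1 - (1 - p)^n_cycles = target`, used to turn 12-month outcome
#' proportions into per-cycle transition probabilities.
#'
#' @param target_cum_prob Cumulative probability over `n_cycles`, in `[0, 1)`.
#' @param n_cycles Number of cycles the target spans.
#' @return Probability per cycle.
#' @export
#' @examples
#' calibrate_cycle_probability(34 / 53, 12)  # 12-month CR proportion
calibrate_cycle_probability <- function(target_cum_prob, n_cycles) {
  if (any(target_cum_prob < 0 | target_cum_prob >= 1)) {
    stop("cumulative target must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(n_cycles >= 1)
  1 - (1 - target_cum_prob)^(1 / n_cycles)
}

#' Jointly calibrate remission and relapse transition probabilities
#'
#' The per-cycle active->CR, active->PR and remission->relapse
#' probabilities are never published; they are identified by requiring the
#' cohort, started in active disease, to occupy the CR, PR and relapse
#' states at 12 cycles in exactly the observed 12-month proportions. The
#' single-risk constant-hazard inversion seeds a multiplicative
#' fixed-point iteration (each cause-specific probability is rescaled by
#' the ratio of its target to its achieved occupancy) that accounts for
#' the competition between the transitions and the small dialysis exits.
#'
#' @param strategy A `strategy` carrying the 12-month targets.
#' @param pt A `param_table`.
#' @param n_cycles Calibration window in cycles (12 = one year).
#' @param tol Convergence tolerance on the occupancy mismatch.
#' @param max_iter Iteration cap.
#' @return List with per-cycle probabilities `p_cr`, `p_pr`, `p_relapse`,
#'   the achieved 12-cycle occupancies, and the iteration count.
#' @export
calibrate_strategy_transitions <- function(strategy, pt, n_cycles = 12,
                                           tol = 1e-10, max_iter = 500L) {
  targets <- strategy$targets
  if (any(targets < 0) || sum(targets) >= 1) {
    stop("12-month targets must be nonnegative and sum to < 1", call. = FALSE)
  }
  p <- c(cr = calibrate_cycle_probability(targets[["cr"]], n_cycles),
         pr = calibrate_cycle_probability(targets[["pr"]], n_cycles),
         relapse = calibrate_cycle_probability(targets[["relapse"]], n_cycles))
  inp <- .matrix_inputs(pt, n_cycles)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    M <- .assemble_matrix(inp, p[["cr"]], p[["pr"]], p[["relapse"]])
    occ <- c(1, rep(0, 7))
    for (t in seq_len(n_cycles)) occ <- as.numeric(occ %*% M)
    achieved <- occ[2:4]
    tv <- unname(targets)
    if (max(abs(achieved - tv)) < tol || iter >= max_iter) break
    achieved[achieved <= 0] <- 1e-300
    ratio <- tv / achieved
    ratio[tv <= 0] <- 0
    p <- p * ratio
    p[p > 0.999999] <- 0.999999
  }
  if (max(abs(achieved - unname(targets))) > 1e-6) {
    stop("calibration failed to converge for strategy ", strategy$name,
         call. = FALSE)
  }
  list(p_cr = unname(p["cr"]), p_pr = unname(p["pr"]),
       p_relapse = unname(p["relapse"]),
       achieved = stats::setNames(achieved, c("cr", "pr", "relapse")),
       iterations = iter)
}

#' Build the per-cycle transition matrix for a strategy
#'
#' Rows follow [health_states()]. Active disease and relapse share the
#' calibrated remission transitions plus the (converted) annual dialysis
#' incidences; CR and PR carry the calibrated relapse transition; the
#' dialysis rows use the published modality-switch, transplant and
#' mortality rates; the transplant row uses the 10-year mortality under a
#' constant hazard; death is absorbing. Residual mass stays in the row
#' state, and a row whose exits exceed one raises an error naming it.
#'
#' @param strategy A `strategy`.
#' @param pt A `param_table`.
#' @param calib Calibrated transitions from
#'   [calibrate_strategy_transitions()] (list with `p_cr`, `p_pr`,
#'   `p_relapse`); computed on the fly when `NULL`.
#' @param cycles_per_year Cycles per model year.
#' @return An 8x8 row-stochastic matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(strategy, pt, calib = NULL,
                                    cycles_per_year = 12) {
  if (is.null(calib)) {
    calib <- calibrate_strategy_transitions(strategy, pt,
                                            n_cycles = cycles_per_year)
  }
  stopifnot(is.numeric(calib$p_cr), is.numeric(calib$p_pr),
            is.numeric(calib$p_relapse))
  .assemble_matrix(.matrix_inputs(pt, cycles_per_year),
                   calib$p_cr, calib$p_pr, calib$p_relapse)
}

# Per-cycle probabilities of the published transitions, converted once per
# parameter set (the calibration loop reassembles the matrix many times).
.matrix_inputs <- function(pt, cycles_per_year = 12) {
  list(p_hd     = .cycle_prob(pt, "transition.hd_incidence", cycles_per_year),
       p_pd     = .cycle_prob(pt, "transition.pd_incidence", cycles_per_year),
       hd_pd    = .cycle_prob(pt, "transition.hd_to_pd", cycles_per_year),
       pd_hd    = .cycle_prob(pt, "transition.pd_to_hd", cycles_per_year),
       kt       = .cycle_prob(pt, "transition.kt_incidence", cycles_per_year),
       hd_death = .cycle_prob(pt, "transition.hd_to_death", cycles_per_year),
       pd_death = .cycle_prob(pt, "transition.pd_to_death", cycles_per_year),
       kt_death = .cycle_prob(pt, "transition.kt_mortality", cycles_per_year))
}

# Fast assembly by numeric state index:
# 1 active, 2 cr, 3 pr, 4 relapse, 5 hd, 6 pd, 7 kt, 8 death.
.assemble_matrix <- function(inp, p_cr, p_pr, p_relapse) {
  states <- health_states()
  exits <- c(p_cr + p_pr + inp$p_hd + inp$p_pd,      # active / relapse
             p_relapse,                              # cr / pr
             inp$hd_pd + inp$kt + inp$hd_death,      # hd
             inp$pd_hd + inp$kt + inp$pd_death,      # pd
             inp$kt_death)                           # kt
  over <- exits > 1 + 1e-12
  if (any(over)) {
    stop("transition row '",
         c("active", "cr", "hd", "pd", "kt")[which(over)[1]],
         "' has exit probability ", signif(exits[which(over)[1]], 6), " > 1",
         call. = FALSE)
  }
  M <- matrix(0, 8, 8, dimnames = list(states, states))
  M[1, ] <- c(1 - exits[1], p_cr, p_pr, 0, inp$p_hd, inp$p_pd, 0, 0)
  M[4, ] <- c(0, p_cr, p_pr, 1 - exits[1], inp$p_hd, inp$p_pd, 0, 0)
  M[2, 2] <- 1 - p_relapse; M[2, 4] <- p_relapse
  M[3, 3] <- 1 - p_relapse; M[3, 4] <- p_relapse
  M[5, ] <- c(0, 0, 0, 0, 1 - exits[3], inp$hd_pd, inp$kt, inp$hd_death)
  M[6, ] <- c(0, 0, 0, 0, inp$pd_hd, 1 - exits[4], inp$kt, inp$pd_death)
  M[7, 7] <- 1 - inp$kt_death; M[7, 8] <- inp$kt_death
  M[8, 8] <- 1
  M
}

#' Propagate a cohort occupancy vector through a transition matrix
#'
#' The bare Markov-chain primitive: left-multiplies the occupancy by the
#' matrix once per cycle. Used by the engine and by tests that compare
#' the cohort trace against per-individual simulation.
#'
#' @param M Square row-stochastic matrix.
#' @param n_cycles Number of cycles to propagate.
#' @param init Initial occupancy (defaults to all mass in state 1).
#' @return `(n_cycles + 1) x k` occupancy matrix, row 1 = `init`.
#' @export
markov_trace <- function(M, n_cycles, init = NULL) {
  k <- nrow(M)
  stopifnot(ncol(M) == k, n_cycles >= 0)
  if (max(abs(rowSums(M) - 1)) > 1e-12 || any(M < 0) || any(M > 1)) {
    stop("matrix is not row-stochastic", call. = FALSE)
  }
  if (is.null(init)) init <- c(1, rep(0, k - 1))
  occ <- matrix(0, n_cycles + 1L, k, dimnames = list(NULL, rownames(M)))
  occ[1L, ] <- init
  for (t in seq_len(n_cycles)) occ[t + 1L, ] <- occ[t, ] %*% M
  occ
}

# State utility vector in model-state order, honouring the relapse-utility knob.
.state_utilities <- function(pt) {
  st <- model_settings(pt)
  u <- param_value(pt, c("utility.active_disease", "utility.complete_remission",
                         "utility.partial_remission", "utility.active_disease",
                         "utility.hemodialysis", "utility.peritoneal_dialysis",
                         "utility.kidney_transplant", "utility.death"))
  names(u) <- health_states()
  relapse_src <- if (is.null(st$relapse_utility)) "active_disease" else st$relapse_utility
  u["relapse"] <- param_value(pt, paste0("utility.", relapse_src))
  u
}

# Annual state-maintenance costs (dialysis, transplant) per cycle.
.state_cycle_costs <- function(pt, cycles_per_year) {
  costs <- stats::setNames(numeric(8), health_states())
  costs["hd"] <- param_value(pt, "cost.hemodialysis_annual") / cycles_per_year
  costs["pd"] <- param_value(pt, "cost.peritoneal_dialysis_annual") / cycles_per_year
  costs["kt"] <- param_value(pt, "cost.kidney_transplant_annual") / cycles_per_year
  costs
}

#' Run the cohort trace for a strategy
#'
#' Starts the whole cohort in active disease, propagates the occupancy by
#' the strategy's transition matrix each cycle, and accrues costs (state
#' maintenance plus the strategy's drug/monitoring/adverse-event schedule)
#' and QALYs (occupancy times state utility times cycle length), both
#' nominally and discounted. Membership is valued at the cycle start
#' unless the half-cycle-correction setting is on, in which case the mean
#' of the start and end occupancy is used.
#'
#' @param strategy A `strategy`.
#' @param pt A `param_table`.
#' @param horizon_years Horizon in years (defaults to the settings value;
#'   capped by the `max_horizon_years` setting).
#' @param conv A `cycle_convention`; derived from the settings when `NULL`.
#' @param calib Optional precomputed calibration.
#' @return A `cohort_trace`: list with the `(n_cycles + 1) x 8` occupancy
#'   matrix and per-cycle nominal/discounted cost and QALY vectors plus
#'   their cumulative sums.
#' @export
#' @examples
#' pt <- load_parameter_table()
#' tr <- run_cohort(strategy_rtx(pt), pt, horizon_years = 1)
#' sum(tr$cycle_qaly_disc)
run_cohort <- function(strategy, pt, horizon_years = NULL, conv = NULL,
                       calib = NULL) {
  st <- model_settings(pt)
  if (is.null(conv)) conv <- .conv_from_settings(pt, horizon_years)
  if (!is.null(st$max_horizon_years) &&
      conv$horizon_years > st$max_horizon_years) {
    stop("horizon ", conv$horizon_years, " years exceeds configured maximum of ",
         st$max_horizon_years, call. = FALSE)
  }
  cpy <- conv$cycles_per_year
  n <- conv$n_cycles
  if (is.null(calib)) {
    calib <- calibrate_strategy_transitions(strategy, pt, n_cycles = cpy)
  }
  M <- build_transition_matrix(strategy, pt, calib, cpy)
  util <- .state_utilities(pt)
  state_cost <- .state_cycle_costs(pt, cpy)
  half_cycle <- isTRUE(st$half_cycle_correction)
  cycle_cost_fn <- .make_cycle_cost(strategy, pt)

  occ <- matrix(0, n + 1L, 8L, dimnames = list(NULL, health_states()))
  occ[1L, "active"] <- 1
  cost <- qaly <- disc <- numeric(n)
  for (t in seq_len(n)) {
    start <- occ[t, ]
    occ[t + 1L, ] <- as.numeric(start %*% M)
    if (abs(sum(occ[t + 1L, ]) - 1) > 1e-10) {
      stop("occupancy row ", t + 1L, " does not sum to 1", call. = FALSE)
    }
    valued <- if (half_cycle) (start + occ[t + 1L, ]) / 2 else start
    cost[t] <- sum(valued * state_cost) + cycle_cost_fn(t, valued)
    qaly[t] <- sum(valued * util) / cpy
    disc[t] <- (1 + conv$discount_rate)^(-t / cpy)
  }
  structure(list(strategy = strategy$name,
                 convention = conv,
                 calibration = calib,
                 occupancy = occ,
                 cycle_cost = cost,
                 cycle_cost_disc = cost * disc,
                 cycle_qaly = qaly,
                 cycle_qaly_disc = qaly * disc,
                 cum_cost = cumsum(cost),
                 cum_cost_disc = cumsum(cost * disc),
                 cum_qaly = cumsum(qaly),
                 cum_qaly_disc = cumsum(qaly * disc)),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- length(x$cycle_cost)
  cat(sprintf(paste0("<cohort_trace %s> %d cycles; discounted totals: ",
                     "cost %.2f, QALY %.4f\n"),
              x$strategy, n, x$cum_cost_disc[n], x$cum_qaly_disc[n]))
  invisible(x)
}

#' Cohort trace as a per-cycle data frame
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return Data frame with one row per cycle: cycle index, the eight
#'   occupancy columns (at the cycle start), nominal and discounted cycle
#'   cost and QALY, and their cumulative sums.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x$cycle_cost)
  out <- data.frame(cycle = seq_len(n),
                    x$occupancy[seq_len(n), , drop = FALSE],
                    cost = x$cycle_cost, cost_disc = x$cycle_cost_disc,
                    qaly = x$cycle_qaly, qaly_disc = x$cycle_qaly_disc,
                    cum_cost = x$cum_cost, cum_cost_disc = x$cum_cost_disc,
                    cum_qaly = x$cum_qaly, cum_qaly_disc = x$cum_qaly_disc)
  rownames(out) <- NULL
  out
}

#' Write a cohort trace to CSV
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

# Cumulative discounted cost/QALY at whole-year marks.
.yearly_cumulative <- function(trace) {
  cpy <- trace$convention$cycles_per_year
  years <- seq_len(trace$convention$horizon_years)
  idx <- years * cpy
  data.frame(year = years,
             cum_cost = trace$cum_cost_disc[idx],
             cum_qaly = trace$cum_qaly_disc[idx])
}
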
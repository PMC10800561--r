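#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full deterministic pipeline twice per parameter — once with
#' the parameter at its lower bound, once at its upper bound, everything
#' else at its mean — and records the resulting ICER. Entries are
#' returned sorted by the absolute ICER span, the tornado-diagram order.
#' The recorded value is the signed ratio `delta_cost / delta_qaly`
#' (negative under dominance); a run with no QALY difference records `NA`.
#'
#' @param pt A `param_table`.
#' @param varied Character vector of parameter names to vary; defaults to
#'   every parameter in the registry (parameters the model never reads,
#'   or with a zero-width range, simply produce a zero span). Parameters
#'   with inverted bounds are skipped with a warning.
#' @param horizon_years Horizon for the reruns.
#' @param wtp Willingness-to-pay threshold (decision bookkeeping only).
#' @return A `tornado` data frame: `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`, plus a `base_icer` attribute.
#' @export
one_way_dsa <- function(pt, varied = NULL, horizon_years = NULL, wtp = NULL) {
  st <- model_settings(pt)
  if (is.null(wtp)) wtp <- st$wtp_per_qaly
  if (is.null(varied)) varied <- pt$name
  idx <- match(varied, pt$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(varied[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  invalid <- pt$low[idx] > pt$high[idx]
  if (any(invalid)) {
    warning("skipping parameter(s) without usable bounds: ",
            paste(varied[invalid], collapse = ", "), call. = FALSE)
    varied <- varied[!invalid]
  }
  ratio_at <- function(ptx) {
    tr_a <- run_cohort(strategy_rtx(ptx), ptx, horizon_years)
    tr_b <- run_cohort(strategy_tac(ptx), ptx, horizon_years)
    res <- compare_strategies(tr_a, tr_b, wtp)
    if (res$delta_qaly == 0) NA_real_ else res$delta_cost / res$delta_qaly
  }
  base <- ratio_at(pt)
  lo <- hi <- numeric(length(varied))
  for (i in seq_along(varied)) {
    nm <- varied[i]
    row <- pt[match(nm, pt$name), ]
    lo[i] <- ratio_at(set_param(pt, stats::setNames(row$low, nm)))
    hi[i] <- ratio_at(set_param(pt, stats::setNames(row$high, nm)))
  }
  out <- data.frame(parameter = varied,
                    low = pt$low[match(varied, pt$name)],
                    high = pt$high[match(varied, pt$name)],
                    icer_at_low = lo, icer_at_high = hi,
                    span = abs(hi - lo))
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, base_icer = base, wtp = wtp, class = c("tornado", "data.frame"))
}

# Beta fit from a mean and standard deviation (method of moments).
.fit_beta_mean_sd <- function(mean, sd) {
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean)) return(fit_fixed(mean))
  nu <- mean * (1 - mean) / v - 1
  structure(list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu,
                 mean = mean, sd = sd),
            class = "fitted_dist")
}

# Beta uncertainty for the calibrated 12-month outcome targets, from the
# binomial standard error of the observed counts.
.target_fits <- function(strategy) {
  n <- strategy$target_counts[["n"]]
  lapply(c(cr = "cr", pr = "pr", relapse = "relapse"), function(k) {
    p <- strategy$targets[[k]]
    .fit_beta_mean_sd(p, sqrt(p * (1 - p) / n))
  })
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the joint parameter uncertainty: each iteration draws
#' every non-fixed parameter from its method-of-moments Beta/Gamma fit and
#' each arm's 12-month outcome proportions from Beta fits of their
#' binomial counts, recalibrates the remission/relapse transitions,
#' reruns both arms over the maximum horizon, and records the cumulative
#' discounted cost and QALYs at each requested yearly horizon. Draws whose
#' sampled outcome proportions are jointly invalid (sum at or above one,
#' or transition rows with exits above one) are rejected and redrawn; the
#' rejection count is reported. Results are bit-exact reproducible for a
#' fixed seed and iteration count.
#'
#' @param pt A `param_table`.
#' @param iterations Number of accepted Monte Carlo draws.
#' @param seed Integer seed controlling all sampling.
#' @param horizons Yearly horizons to record (subset of 1..max horizon).
#' @param wtp Willingness-to-pay threshold used for the acceptability
#'   summary.
#' @param sample_targets Sample the 12-month outcome proportions from
#'   their binomial uncertainty (default); `FALSE` holds them at the
#'   observed point estimates.
#' @return A `psa_result`: list with `samples` (one row per draw per
#'   horizon: per-arm discounted cost/QALY and the incrementals), `ceac`
#'   (probability cost-effective per horizon at `wtp`), `rejected`,
#'   `iterations`, `seed`, `wtp`.
#' @export
#' @examples
#' pt <- load_parameter_table()
#' psa <- run_psa(pt, iterations = 20, seed = 1)
#' psa$ceac
run_psa <- function(pt, iterations, seed, horizons = 1:5, wtp = NULL,
                    sample_targets = TRUE) {
  st <- model_settings(pt)
  if (is.null(wtp)) wtp <- st$wtp_per_qaly
  stopifnot(iterations >= 1)
  max_h <- max(horizons)
  cpy <- st$cycles_per_year
  fits <- fit_parameter_distributions(pt)
  sampled <- names(fits)[vapply(fits, function(f) f$family != "fixed", logical(1))]
  s_rtx <- strategy_rtx(pt)
  s_tac <- strategy_tac(pt)
  tf <- list(rtx = .target_fits(s_rtx), tac = .target_fits(s_tac))

  rows <- vector("list", iterations)
  rejected <- 0L
  .with_seed(seed, {
    for (i in seq_len(iterations)) {
      repeat {
        draw <- vapply(sampled, function(nm) sample_dist(fits[[nm]], 1L),
                       numeric(1))
        tg <- if (sample_targets) {
          lapply(tf, function(arm_fits) {
            vapply(arm_fits, function(f) sample_dist(f, 1L), numeric(1))
          })
        } else {
          list(rtx = s_rtx$targets, tac = s_tac$targets)
        }
        if (any(vapply(tg, sum, numeric(1)) >= 1)) { rejected <- rejected + 1L; next }
        ptx <- set_param(pt, draw)
        res <- tryCatch({
          sr <- s_rtx; sr$targets <- tg$rtx
          stc <- s_tac; stc$targets <- tg$tac
          tr_a <- run_cohort(sr, ptx, max_h)
          tr_b <- run_cohort(stc, ptx, max_h)
          idx <- horizons * cpy
          data.frame(draw = i, horizon = horizons,
                     cost_rtx = tr_a$cum_cost_disc[idx],
                     qaly_rtx = tr_a$cum_qaly_disc[idx],
                     cost_tac = tr_b$cum_cost_disc[idx],
                     qaly_tac = tr_b$cum_qaly_disc[idx])
        }, error = function(e) NULL)
        if (is.null(res)) { rejected <- rejected + 1L; next }
        rows[[i]] <- res
        break
      }
    }
  })
  samples <- do.call(rbind, rows)
  samples$delta_cost <- samples$cost_rtx - samples$cost_tac
  samples$delta_qaly <- samples$qaly_rtx - samples$qaly_tac
  structure(list(samples = samples,
                 ceac = ceac_curve(samples, wtp = wtp, horizons = horizons),
                 rejected = rejected, iterations = iterations, seed = seed,
                 wtp = wtp),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (%d rejected), seed %s\n", x$iterations,
              x$rejected, format(x$seed)))
  print(x$ceac)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws in which the intervention has the higher net
#' monetary benefit, per horizon and willingness-to-pay value.
#'
#' @param samples PSA samples data frame (see [run_psa()]), with columns
#'   `horizon`, `delta_cost`, `delta_qaly`.
#' @param wtp Numeric vector of willingness-to-pay values.
#' @param horizons Horizons to include; defaults to those present.
#' @return Data frame with columns `horizon`, `wtp`,
#'   `prob_cost_effective`.
#' @export
ceac_curve <- function(samples, wtp, horizons = sort(unique(samples$horizon))) {
  grid <- expand.grid(horizon = horizons, wtp = wtp)
  grid$prob_cost_effective <- mapply(function(h, w) {
    s <- samples[samples$horizon == h, ]
    mean(w * s$delta_qaly - s$delta_cost > 0)
  }, grid$horizon, grid$wtp)
  grid
}

#' Cost-effectiveness plane scatter data
#'
#' @param samples PSA samples data frame (see [run_psa()]).
#' @param horizon Single horizon (years) to extract.
#' @param wtp Threshold-line slope to attach.
#' @return Data frame of `(delta_qaly, delta_cost)` pairs with attributes
#'   `wtp` (threshold-line slope) and `quadrants` (draw counts by
#'   incremental-cost/incremental-QALY sign, summing to the draw total).
#' @export
ce_plane_export <- function(samples, horizon, wtp) {
  s <- samples[samples$horizon == horizon, ]
  if (nrow(s) == 0L) stop("no PSA samples at horizon ", horizon, call. = FALSE)
  quadrants <- c(
    ne = sum(s$delta_qaly >= 0 & s$delta_cost >= 0),
    se = sum(s$delta_qaly >= 0 & s$delta_cost < 0),
    nw = sum(s$delta_qaly < 0 & s$delta_cost >= 0),
    sw = sum(s$delta_qaly < 0 & s$delta_cost < 0))
  structure(data.frame(delta_qaly = s$delta_qaly, delta_cost = s$delta_cost),
            wtp = wtp, quadrants = quadrants)
}

#' Tornado diagram
#'
#' @param tornado A `tornado` data frame from [one_way_dsa()].
#' @param top Number of leading parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15) {
  td <- utils::head(tornado[tornado$span > 0, ], top)
  td$parameter <- factor(td$parameter, levels = rev(td$parameter))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(td) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (yuan per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' @param samples PSA samples data frame.
#' @param wtp Threshold-line slope.
#' @return A ggplot object, faceted by horizon.
#' @export
plot_ce_plane <- function(samples, wtp) {
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, colour = "red") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::facet_wrap(~horizon, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (yuan)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac Data frame from [ceac_curve()].
#' @return A ggplot object (probability vs WTP, one line per horizon, or
#'   vs horizon when a single WTP is present).
#' @export
plot_ceac <- function(ceac) {
  if (length(unique(ceac$wtp)) == 1L) {
    ggplot2::ggplot(ceac, ggplot2::aes(x = .data$horizon,
                                       y = .data$prob_cost_effective)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Horizon (years)",
                    y = "Probability cost-effective") +
      ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp,
                                       y = .data$prob_cost_effective,
                                       colour = factor(.data$horizon))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Willingness to pay (yuan per QALY)",
                    y = "Probability cost-effective", colour = "Horizon") +
      ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  }
}
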
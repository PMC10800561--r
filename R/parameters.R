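#' Health states of the cohort model
#'
#' The model follows a treated membranous-nephropathy cohort through eight
#' mutually exclusive states: active disease (model entry), complete and
#' partial remission, relapse, the two dialysis modalities, kidney
#' transplant, and death (absorbing).
#'
#' @return Character vector of the eight state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("active", "cr", "pr", "relapse", "hd", "pd", "kt", "death")
}

.valid_families   <- c("beta", "gamma", "fixed")
.valid_categories <- c("probability", "rate", "utility", "cost", "incidence")
.valid_time_basis <- c("per_year", "per_cycle", "per_event", "per_6_months",
                       "per_10_years", "dimensionless")

#' Path to the packaged default parameter file
#'
#' @return Path to the YAML document holding the published model inputs.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "parameters.yaml", package = "pmncea", mustWork = TRUE)
}

# One flattened parameter row with defaults applied and checked.
.param_row <- function(name, entry, category, time_basis, range_frac) {
  if (!is.list(entry) || is.null(entry$mean)) {
    stop("malformed parameter entry '", name, "': needs a 'mean' field",
         call. = FALSE)
  }
  mean <- as.numeric(entry$mean)
  family <- if (is.null(entry$family)) "fixed" else as.character(entry$family)
  tb <- if (is.null(entry$time_basis)) time_basis else as.character(entry$time_basis)
  if (!family %in% .valid_families) {
    stop("parameter '", name, "': unknown family '", family, "'", call. = FALSE)
  }
  if (!tb %in% .valid_time_basis) {
    stop("parameter '", name, "': unknown time basis '", tb, "'", call. = FALSE)
  }
  has_range <- !is.null(entry$low) && !is.null(entry$high)
  if (has_range) {
    low <- as.numeric(entry$low); high <- as.numeric(entry$high)
  } else {
    low  <- mean * (1 - range_frac)
    high <- mean * (1 + range_frac)
  }
  if (low > mean || mean > high) {
    stop("parameter '", name, "': mean ", mean, " outside range [",
         low, ", ", high, "]", call. = FALSE)
  }
  if (category %in% c("probability", "incidence") &&
      (mean < 0 || mean > 1 || low < 0 || high > 1)) {
    stop("parameter '", name, "': ", category, " values must lie in [0, 1]",
         call. = FALSE)
  }
  if (category == "utility" && (mean < 0 || mean > 1)) {
    stop("parameter '", name, "': utility must lie in [0, 1]", call. = FALSE)
  }
  if (category == "cost" && low < 0) {
    stop("parameter '", name, "': costs must be nonnegative", call. = FALSE)
  }
  if (family == "beta" && !category %in% c("probability", "utility", "incidence")) {
    stop("parameter '", name, "': Beta family is only valid for ",
         "probabilities, utilities and incidences", call. = FALSE)
  }
  if (family == "gamma" && category != "cost") {
    stop("parameter '", name, "': Gamma family is only valid for costs",
         call. = FALSE)
  }
  data.frame(name = name, mean = mean, low = low, high = high,
             family = family, category = category, time_basis = tb,
             source = if (is.null(entry$source)) "" else as.character(entry$source),
             stringsAsFactors = FALSE)
}

#' Load the typed model parameter table
#'
#' Reads the hierarchical parameter document (sections `transition_rates`,
#' `utilities`, `ae_incidence`, `ae_costs`, `direct_costs`, `settings`,
#' `outcome_targets`) into a flat registry, one row per parameter, with the
#' distribution family and category checked on entry. Entries without a
#' printed range receive a +/-20% band (used by one-way sensitivity
#' analysis) but remain `fixed` for probabilistic sampling.
#'
#' @param path Path to a YAML parameter document; defaults to the packaged
#'   file reproducing the published input table.
#' @return A `param_table`: a data frame with columns `name`, `mean`,
#'   `low`, `high`, `family`, `category`, `time_basis`, `source`, plus
#'   `settings` and `outcome_targets` attributes.
#' @export
#' @examples
#' pt <- load_parameter_table()
#' param_value(pt, "utility.complete_remission")
load_parameter_table <- function(path = default_parameter_file()) {
  doc <- yaml::read_yaml(path)
  required <- c("settings", "transition_rates", "utilities", "ae_incidence",
                "ae_costs", "direct_costs", "outcome_targets")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("parameter document lacks section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frac <- doc$settings$default_range_fraction
  if (is.null(frac)) frac <- 0.20

  rows <- list()
  add <- function(prefix, entries, category, tb) {
    for (nm in names(entries)) {
      rows[[length(rows) + 1L]] <<-
        .param_row(paste0(prefix, nm), entries[[nm]], category, tb, frac)
    }
  }
  add("transition.", doc$transition_rates, "probability", "per_year")
  add("utility.",    doc$utilities,        "utility",     "dimensionless")
  add("ae_incidence.rtx.", doc$ae_incidence$rtx, "incidence", "per_event")
  add("ae_incidence.tac.", doc$ae_incidence$tac, "incidence", "per_event")
  add("ae_cost.",    doc$ae_costs,     "cost", "per_event")
  add("cost.",       doc$direct_costs, "cost", "per_event")

  pt <- do.call(rbind, rows)
  rownames(pt) <- pt$name
  for (arm in c("rtx", "tac")) {
    tg <- doc$outcome_targets[[arm]]
    if (is.null(tg$size) || is.null(tg$cr) || is.null(tg$pr) || is.null(tg$relapse)) {
      stop("outcome_targets$", arm, " needs size, cr, pr, relapse counts",
           call. = FALSE)
    }
  }
  structure(pt,
            settings = doc$settings,
            outcome_targets = doc$outcome_targets,
            class = c("param_table", "data.frame"))
}

#' Look up parameter values by name
#'
#' @param pt A `param_table`.
#' @param name Character vector of parameter names.
#' @return Numeric vector of mean values (named when `name` has length > 1).
#' @export
param_value <- function(pt, name) {
  idx <- match(name, pt$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(name[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  v <- pt$mean[idx]
  if (length(name) > 1L) names(v) <- name
  v
}

#' Replace parameter point values
#'
#' Used by the sensitivity analyses to push a parameter to a bound or to a
#' sampled value while leaving the rest of the registry untouched.
#'
#' @param pt A `param_table`.
#' @param values Named numeric vector of replacement means.
#' @return The modified `param_table`.
#' @export
set_param <- function(pt, values) {
  idx <- match(names(values), pt$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  pt$mean[idx] <- as.numeric(values)
  pt
}

#' Model settings stored with a parameter table
#'
#' @param pt A `param_table`.
#' @return Named list of settings (cycle structure, discount rate, WTP,
#'   dosing knobs, monitoring schedule).
#' @export
model_settings <- function(pt) attr(pt, "settings")

#' Export the parameter registry as CSV
#'
#' @param pt A `param_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_parameter_table <- function(pt, path) {
  utils::write.csv(as.data.frame(pt), path, row.names = FALSE)
  invisible(path)
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p)^(1/cycles_per_year)`, so that
#' compounding over one year of cycles recovers the annual probability.
#'
#' @param p_annual Probability per year, in `[0, 1)`.
#' @param cycles_per_year Number of model cycles per year (12 for 30-day
#'   cycles on a 360-day model year).
#' @return Probability per cycle.
#' @export
#' @examples
#' annual_prob_to_cycle_prob(0.0422)  # hemodialysis -> death, monthly
annual_prob_to_cycle_prob <- function(p_annual, cycles_per_year = 12) {
  if (any(p_annual < 0 | p_annual >= 1)) {
    stop("annual probability must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' @rdname annual_prob_to_cycle_prob
#' @param p_cycle Probability per cycle, in `[0, 1)`.
#' @export
cycle_prob_to_annual_prob <- function(p_cycle, cycles_per_year = 12) {
  if (any(p_cycle < 0 | p_cycle >= 1)) {
    stop("cycle probability must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - p_cycle)^cycles_per_year
}

#' Convert a multi-year cumulative probability to an annual probability
#'
#' Used for the 10-year post-transplant mortality, which is converted to an
#' annual probability under a constant hazard before the usual
#' annual-to-cycle step.
#'
#' @param p Cumulative probability over `years` years, in `[0, 1)`.
#' @param years Number of years the probability spans.
#' @return Annual probability.
#' @export
multiyear_prob_to_annual <- function(p, years) {
  if (any(p < 0 | p >= 1)) stop("probability must lie in [0, 1)", call. = FALSE)
  1 - (1 - p)^(1 / years)
}

# Per-cycle probability for a parameter row, honouring its time basis.
.cycle_prob <- function(pt, name, cycles_per_year = 12) {
  idx <- match(name, pt$name)
  if (is.na(idx)) stop("unknown parameter: ", name, call. = FALSE)
  p <- pt$mean[idx]
  switch(pt$time_basis[idx],
    per_year     = annual_prob_to_cycle_prob(p, cycles_per_year),
    per_10_years = annual_prob_to_cycle_prob(multiyear_prob_to_annual(p, 10),
                                             cycles_per_year),
    per_cycle    = p,
    stop("parameter '", name, "' has no per-cycle interpretation",
         call. = FALSE))
}

#' Method-of-moments Beta fit from a mean and a printed range
#'
#' The range is read as a central 95% interval, `sd = (high - low) / 3.92`,
#' and the Beta shape parameters are recovered by matching the first two
#' moments. The fit is rejected (error) when the implied variance reaches
#' the Bernoulli bound `mean * (1 - mean)`, where no Beta distribution
#' exists; callers may then fall back to a fixed parameter.
#'
#' @param mean Target mean in (0, 1).
#' @param low,high Range bounds, `0 <= low < high <= 1`.
#' @return A `fitted_dist` with elements `family = "beta"`, `shape1`,
#'   `shape2`, `mean`, `sd`.
#' @export
#' @examples
#' fit_beta_from_mean_range(0.86, 0.63, 1.00)
fit_beta_from_mean_range <- function(mean, low, high) {
  if (!(mean > 0 && mean < 1)) stop("mean must lie in (0, 1)", call. = FALSE)
  if (!(low >= 0 && low <= mean && mean <= high && high <= 1 && low < high)) {
    stop("need 0 <= low <= mean <= high <= 1 with low < high", call. = FALSE)
  }
  s <- (high - low) / (2 * 1.96)
  v <- s^2
  if (v >= mean * (1 - mean)) {
    stop("implied variance ", signif(v, 6), " >= mean*(1-mean); ",
         "no Beta fit exists", call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  structure(list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu,
                 mean = mean, sd = s),
            class = "fitted_dist")
}

#' Method-of-moments Gamma fit from a mean and a printed range
#'
#' As for the Beta fit, the range is read as a 95% interval:
#' `sd = (high - low) / 3.92`, `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param mean Target mean, positive.
#' @param low,high Range bounds, `0 <= low < high`.
#' @return A `fitted_dist` with elements `family = "gamma"`, `shape`,
#'   `scale`, `mean`, `sd`.
#' @export
fit_gamma_from_mean_range <- function(mean, low, high) {
  if (mean <= 0) stop("mean must be positive", call. = FALSE)
  if (!(low >= 0 && low <= mean && mean <= high && low < high)) {
    stop("need 0 <= low <= mean <= high with low < high", call. = FALSE)
  }
  s <- (high - low) / (2 * 1.96)
  structure(list(family = "gamma", shape = (mean / s)^2, scale = s^2 / mean,
                 mean = mean, sd = s),
            class = "fitted_dist")
}

#' A degenerate (fixed-value) parameter distribution
#' @param mean The fixed value.
#' @return A `fitted_dist` with `family = "fixed"`.
#' @export
fit_fixed <- function(mean) {
  structure(list(family = "fixed", mean = mean, sd = 0), class = "fitted_dist")
}

#' @export
print.fitted_dist <- function(x, ...) {
  pars <- switch(x$family,
    beta  = sprintf("shape1 = %.4f, shape2 = %.4f", x$shape1, x$shape2),
    gamma = sprintf("shape = %.4f, scale = %.4f", x$shape, x$scale),
    fixed = "")
  cat(sprintf("<fitted_dist %s> mean = %g, sd = %g %s\n",
              x$family, x$mean, x$sd,
              if (nzchar(pars)) paste0("(", pars, ")") else ""))
  invisible(x)
}

#' Draw random samples from a fitted parameter distribution
#'
#' @param fd A `fitted_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`; Beta draws lie in `[0, 1]`, Gamma
#'   draws are nonnegative, fixed distributions repeat the mean.
#' @export
sample_dist <- function(fd, n) {
  switch(fd$family,
    beta  = stats::rbeta(n, fd$shape1, fd$shape2),
    gamma = stats::rgamma(n, shape = fd$shape, scale = fd$scale),
    fixed = rep(fd$mean, n))
}

#' Fit sampling distributions for every parameter in the registry
#'
#' Beta-family rows get a method-of-moments Beta fit from their range,
#' Gamma-family rows a Gamma fit, and fixed rows a degenerate distribution.
#' A Beta fit that fails (variance at the Bernoulli bound) falls back to
#' fixed with a warning.
#'
#' @param pt A `param_table`.
#' @return Named list of `fitted_dist` objects, one per parameter row.
#' @export
fit_parameter_distributions <- function(pt) {
  fits <- vector("list", nrow(pt))
  names(fits) <- pt$name
  for (i in seq_len(nrow(pt))) {
    fits[[i]] <- switch(pt$family[i],
      fixed = fit_fixed(pt$mean[i]),
      gamma = fit_gamma_from_mean_range(pt$mean[i], pt$low[i], pt$high[i]),
      beta  = tryCatch(
        fit_beta_from_mean_range(pt$mean[i], pt$low[i], pt$high[i]),
        error = function(e) {
          warning("parameter '", pt$name[i], "': ", conditionMessage(e),
                  "; treated as fixed", call. = FALSE)
          fit_fixed(pt$mean[i])
        }))
  }
  fits
}
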
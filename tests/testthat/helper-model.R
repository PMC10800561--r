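# Shared fixtures for the test suite. The parameter table is loaded once;
# tests that perturb it work on copies.

base_params <- load_parameter_table()

# Parameter table with selected settings overridden.
with_settings <- function(pt, ...) {
  st <- attr(pt, "settings")
  st[names(list(...))] <- list(...)
  attr(pt, "settings") <- st
  pt
}

# Minimal cohort_trace stand-in with prescribed per-cycle discounted
# accruals, for exercising the CEA layer in isolation.
fake_trace <- function(cycle_cost, cycle_qaly, name = "X",
                       cycles_per_year = 12) {
  n <- length(cycle_cost)
  conv <- cycle_convention(horizon_years = n / cycles_per_year,
                           cycles_per_year = cycles_per_year,
                           discount_rate = 0)
  structure(list(strategy = name, convention = conv,
                 cycle_cost = cycle_cost, cycle_cost_disc = cycle_cost,
                 cycle_qaly = cycle_qaly, cycle_qaly_disc = cycle_qaly,
                 cum_cost = cumsum(cycle_cost),
                 cum_cost_disc = cumsum(cycle_cost),
                 cum_qaly = cumsum(cycle_qaly),
                 cum_qaly_disc = cumsum(cycle_qaly)),
            class = "cohort_trace")
}

# Random valid 2x2 table with all margins positive.
random_2x2 <- function() {
  repeat {
    m <- matrix(rpois(4, lambda = sample(3:40, 1)), 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Randomly perturb every ranged parameter uniformly within its bounds.
perturb_params <- function(pt) {
  ranged <- pt$low < pt$high
  vals <- stats::runif(sum(ranged), pt$low[ranged], pt$high[ranged])
  set_param(pt, stats::setNames(vals, pt$name[ranged]))
}
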
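test_that("single-target calibration inverts cumulative probabilities", {
  expect_identical(calibrate_cycle_probability(0, 12), 0)
  p <- calibrate_cycle_probability(0.6415, 12)
  expect_equal(p, 0.081932, tolerance = 1e-4)
  expect_equal(1 - (1 - p)^12, 0.6415, tolerance = 1e-9)
  p2 <- calibrate_cycle_probability(0.2286, 12)
  expect_equal(p2, 0.0213968, tolerance = 1e-5)
  expect_equal(1 - (1 - p2)^12, 0.2286, tolerance = 1e-9)
  expect_error(calibrate_cycle_probability(1, 12), "\\[0, 1\\)")
})

test_that("joint calibration reproduces both arms' 12-month occupancies", {
  pt <- base_params
  for (s in list(strategy_rtx(pt), strategy_tac(pt))) {
    cal <- calibrate_strategy_transitions(s, pt)
    M <- build_transition_matrix(s, pt, cal)
    occ <- markov_trace(M, 12)[13, ]
    expect_equal(unname(occ[c("cr", "pr", "relapse")]),
                 unname(s$targets), tolerance = 1e-6)
  }
})

test_that("transition matrices are row-stochastic with correct structure", {
  pt <- base_params
  s <- strategy_rtx(pt)
  M <- build_transition_matrix(s, pt)
  expect_equal(unname(rowSums(M)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
  # death absorbing
  expect_equal(unname(M["death", ]), c(0, 0, 0, 0, 0, 0, 0, 1))
  # hemodialysis row: converted published annual rates
  expect_equal(M["hd", "death"], 1 - (1 - 0.0422)^(1 / 12), tolerance = 1e-12)
  expect_equal(M["hd", "pd"], 1 - (1 - 0.0032)^(1 / 12), tolerance = 1e-12)
  expect_equal(M["hd", "kt"], 1 - (1 - 0.0794)^(1 / 12), tolerance = 1e-12)
  # active and relapse share the calibrated remission exits
  expect_equal(M["active", "cr"], M["relapse", "cr"])
  expect_equal(M["active", "pr"], M["relapse", "pr"])
})

test_that("zero calibration targets leave the disease rows inert", {
  pt <- base_params
  s <- strategy_rtx(pt)
  M <- build_transition_matrix(s, pt,
                               calib = list(p_cr = 0, p_pr = 0, p_relapse = 0))
  expect_equal(M["active", "cr"], 0)
  expect_equal(M["active", "pr"], 0)
  # residual after the (tiny) dialysis exits stays in active
  expect_equal(M["active", "active"],
               1 - M["active", "hd"] - M["active", "pd"], tolerance = 1e-15)
  expect_equal(M["cr", "cr"], 1)
})

test_that("rows whose exits exceed one are rejected by name", {
  pt <- base_params
  s <- strategy_rtx(pt)
  expect_error(
    build_transition_matrix(s, pt,
                            calib = list(p_cr = 0.7, p_pr = 0.4,
                                         p_relapse = 0)),
    "row 'active'")
})

test_that("a closed no-death configuration conserves exactly one QALY per year", {
  pt <- base_params
  pt <- set_param(pt, c(transition.kt_mortality = 0,
                        transition.hd_to_death = 0,
                        transition.pd_to_death = 0))
  utils <- pt$name[pt$category == "utility"]
  pt <- set_param(pt, stats::setNames(rep(1, length(utils)), utils))
  pt <- with_settings(pt, discount_rate = 0)
  tr <- run_cohort(strategy_rtx(pt), pt, horizon_years = 5)
  expect_equal(tr$cum_qaly[60], 5, tolerance = 1e-9)
  expect_equal(tr$cum_qaly_disc[60], 5, tolerance = 1e-9)
})

test_that("discounting multiplies cycle-12 accrual by exactly 1/1.05", {
  pt <- base_params
  tr <- run_cohort(strategy_tac(pt), pt, horizon_years = 2)
  expect_gt(tr$cycle_cost[12], 0)
  expect_equal(tr$cycle_cost_disc[12] / tr$cycle_cost[12], 1 / 1.05,
               tolerance = 1e-12)
  expect_equal(tr$cycle_qaly_disc[24] / tr$cycle_qaly[24], 1 / 1.05^2,
               tolerance = 1e-12)
})

test_that("cohort traces conserve mass and accumulate monotonically", {
  pt <- base_params
  for (s in list(strategy_rtx(pt), strategy_tac(pt))) {
    tr <- run_cohort(s, pt, horizon_years = 5)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 61), tolerance = 1e-10)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
    expect_true(all(diff(tr$cum_cost_disc) >= 0))
    expect_true(all(diff(tr$cum_qaly_disc) >= 0))
    # discounting can only shrink totals
    expect_lt(tr$cum_cost_disc[60], tr$cum_cost[60])
    expect_lt(tr$cum_qaly_disc[60], tr$cum_qaly[60])
  }
})

test_that("expected adverse-event cost sums incidence times unit cost", {
  pt <- base_params
  expect_equal(expected_ae_cost(ae_profile(strategy_rtx(pt), pt)), 150.20,
               tolerance = 1e-4)
  expect_equal(expected_ae_cost(ae_profile(strategy_tac(pt), pt)), 1248.37,
               tolerance = 1e-4)
  empty <- data.frame(ae = character(), incidence = numeric(),
                      cost = numeric())
  expect_identical(expected_ae_cost(empty), 0)
  expect_error(expected_ae_cost(data.frame(incidence = -0.1, cost = 1)),
               "\\[0, 1\\]")
  expect_error(expected_ae_cost(data.frame(incidence = 0.1, cost = -1)),
               "nonnegative")
})

test_that("strategy_cycle_cost matches the engine's internal schedule", {
  pt <- base_params
  s <- strategy_rtx(pt)
  occ <- c(0.2, 0.4, 0.3, 0.05, 0.02, 0.01, 0.01, 0.01)
  # full induction split over cycles 1-2: 4 doses x 7 vials x vial price
  vial <- param_value(pt, "cost.rtx_vial")
  c1 <- strategy_cycle_cost(s, pt, 1, occ)
  c2 <- strategy_cycle_cost(s, pt, 2, occ)
  eac <- expected_ae_cost(ae_profile(s, pt))
  visit <- 47 + 44 + 9 + 55
  expect_equal(c1, 14 * vial + eac + visit * sum(occ[1:4]), tolerance = 1e-9)
  expect_equal(c2, 14 * vial, tolerance = 1e-9)
  # second course at cycle 6 weighted by the PR fraction
  c6 <- strategy_cycle_cost(s, pt, 6, occ)
  expect_equal(c6, occ[3] * (28 * vial + eac) + visit * sum(occ[1:4]),
               tolerance = 1e-9)
  # no rituximab cost after the treatment phase
  expect_equal(strategy_cycle_cost(s, pt, 13, occ), 0)
})

test_that("horizon beyond the configured maximum is refused", {
  expect_error(run_cohort(strategy_rtx(base_params), base_params,
                          horizon_years = 6),
               "exceeds configured maximum")
})

test_that("trace exports round-trip through CSV", {
  tr <- run_cohort(strategy_tac(base_params), base_params, horizon_years = 1)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read.csv(f)
  expect_identical(nrow(back), 12L)
  expect_equal(back$cum_qaly_disc[12], tr$cum_qaly_disc[12], tolerance = 1e-12)
  expect_true(all(health_states() %in% names(back)))
})
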
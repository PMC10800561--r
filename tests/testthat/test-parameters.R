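test_that("annual/cycle probability conversion round-trips and is monotone", {
  p <- c(0, 1e-6, seq(0.001, 0.999, length.out = 200))
  back <- cycle_prob_to_annual_prob(annual_prob_to_cycle_prob(p), 12)
  expect_equal(back, p, tolerance = 1e-12)
  pc <- annual_prob_to_cycle_prob(p)
  expect_true(all(diff(pc) > 0))
  expect_identical(annual_prob_to_cycle_prob(0), 0)
  expect_error(annual_prob_to_cycle_prob(1), "\\[0, 1\\)")
  expect_error(cycle_prob_to_annual_prob(-0.1), "\\[0, 1\\)")
})

test_that("published annual rates convert to the expected monthly values", {
  # hemodialysis -> death, 0.0422/year
  expect_equal(annual_prob_to_cycle_prob(0.0422), 1 - 0.9578^(1 / 12),
               tolerance = 1e-12)
  expect_equal(annual_prob_to_cycle_prob(0.0422), 0.00358658, tolerance = 1e-6)
  # 10-year post-transplant mortality 0.425: two-step constant hazard
  pa <- multiyear_prob_to_annual(0.425, 10)
  expect_equal(pa, 0.05383521, tolerance = 1e-7)
  pm <- annual_prob_to_cycle_prob(pa)
  expect_equal(pm, 0.00460093, tolerance = 1e-6)
  # compounding over 120 cycles recovers the 10-year probability
  expect_equal(1 - (1 - pm)^120, 0.425, tolerance = 1e-9)
})

test_that("Beta fits match method-of-moments closed forms and their moments", {
  fd <- fit_beta_from_mean_range(0.86, 0.63, 1.00)
  expect_equal(fd$sd, (1 - 0.63) / 3.92, tolerance = 1e-12)
  expect_equal(fd$shape1, 10.7623, tolerance = 1e-4)
  expect_equal(fd$shape2, 1.7520, tolerance = 1e-4)
  expect_equal(fd$shape1 / (fd$shape1 + fd$shape2), 0.86, tolerance = 1e-6)

  sym <- fit_beta_from_mean_range(0.5, 0.3, 0.7)
  expect_equal(sym$shape1, sym$shape2, tolerance = 1e-12)

  rash <- fit_beta_from_mean_range(0.0377, 0.03, 0.045)
  # moment oracle: numerical integration of the fitted density
  m1 <- integrate(function(x) x * dbeta(x, rash$shape1, rash$shape2), 0, 1,
                  rel.tol = 1e-10)$value
  expect_equal(m1, 0.0377, tolerance = 1e-6)
  m2 <- integrate(function(x) (x - 0.0377)^2 * dbeta(x, rash$shape1, rash$shape2),
                  0, 1, rel.tol = 1e-10)$value
  expect_equal(sqrt(m2), rash$sd, tolerance = 1e-6)

  # implied variance at/above the Bernoulli bound has no Beta fit
  expect_error(fit_beta_from_mean_range(0.02, 0, 1), "no Beta fit")
  expect_error(fit_beta_from_mean_range(0.5, 0.6, 0.9), "low <= mean")
})

test_that("Gamma fits match method-of-moments closed forms", {
  fd <- fit_gamma_from_mean_range(7400, 5920, 8880)
  expect_equal(fd$sd, 755.102, tolerance = 1e-3)
  expect_equal(fd$shape, 96.04, tolerance = 1e-3)
  expect_equal(fd$scale, 77.0512, tolerance = 1e-3)
  expect_equal(fd$shape * fd$scale, 7400, tolerance = 1e-6)

  # range m +/- 1.96 * 0.1 m gives coefficient of variation 0.1
  m <- 123.4
  cv <- fit_gamma_from_mean_range(m, m * (1 - 1.96 * 0.1), m * (1 + 1.96 * 0.1))
  expect_equal(cv$sd / cv$mean, 0.1, tolerance = 1e-12)

  vial <- fit_gamma_from_mean_range(1366.2, 1093, 1639)
  expect_equal(vial$shape * vial$scale, 1366.2, tolerance = 1e-6)
  expect_error(fit_gamma_from_mean_range(-5, 0, 1), "positive")
})

test_that("fitted distributions sample on the right support with the right mean", {
  set.seed(101)
  for (fd in list(fit_beta_from_mean_range(0.738, 0.422, 1.0),
                  fit_gamma_from_mean_range(40678, 32542.4, 48813.6))) {
    x <- sample_dist(fd, 2e5)
    if (fd$family == "beta") expect_true(all(x >= 0 & x <= 1))
    if (fd$family == "gamma") expect_true(all(x >= 0))
    expect_lt(abs(mean(x) - fd$mean), 3 * fd$sd / sqrt(length(x)))
  }
  expect_identical(sample_dist(fit_fixed(3.5), 4), rep(3.5, 4))
})

test_that("the shipped parameter table carries one row per published entry", {
  pt <- base_params
  expected <- c(
    paste0("transition.", c("pd_to_hd", "hd_to_pd", "dialysis_incidence",
                            "hd_incidence", "pd_incidence", "kt_incidence",
                            "hd_to_death", "pd_to_death", "kt_mortality")),
    paste0("utility.", c("complete_remission", "partial_remission",
                         "active_disease", "esrd", "conservative",
                         "hemodialysis", "peritoneal_dialysis",
                         "kidney_transplant", "death")),
    paste0("ae_incidence.rtx.", c("rash", "fever", "gi_infection", "pneumonia")),
    paste0("ae_incidence.tac.", c("severe_pneumonia", "lung_abscess",
                                  "interstitial_pneumonia", "hyperglycemia")),
    paste0("ae_cost.", c("rash", "fever", "gi_infection", "pneumonia",
                         "severe_pneumonia", "lung_abscess",
                         "interstitial_pneumonia", "hyperglycemia")),
    paste0("cost.", c("hemodialysis_annual", "peritoneal_dialysis_annual",
                      "kidney_transplant_annual", "rtx_vial", "tac_6mo_cr",
                      "tac_6mo_pr", "tac_6mo_nr", "tac_6mo_relapse",
                      "methylprednisolone_4mg_tab", "urinalysis",
                      "rapid_proteinuria_test", "quant_proteinuria_test",
                      "liver_function_test")))
  expect_setequal(pt$name, expected)
  expect_false(anyDuplicated(pt$name) > 0)
  # spot-check printed values and typing
  expect_equal(param_value(pt, "utility.complete_remission"), 0.86)
  expect_equal(as.numeric(pt["cost.hemodialysis_annual", c("low", "high")]),
               c(32542.4, 48813.6))
  expect_identical(pt["cost.rtx_vial", "family"], "gamma")
  expect_identical(pt["utility.active_disease", "family"], "beta")
  st <- model_settings(pt)
  expect_equal(st$discount_rate, 0.05)
  expect_equal(st$wtp_per_qaly, 257094)
})

test_that("malformed parameter documents are rejected with named errors", {
  doc <- yaml::read_yaml(default_parameter_file())
  bad <- doc
  bad$transition_rates$pd_to_hd$mean <- 1.2     # probability > 1
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_parameter_table(f), "transition.pd_to_hd")

  bad <- doc
  bad$utilities$hemodialysis$mean <- 0.2        # below its printed range
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_parameter_table(f), "outside range")

  bad <- doc
  bad$ae_costs$rash$family <- "lognormal"       # unsupported family
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_parameter_table(f), "unknown family")

  bad <- doc
  bad$direct_costs$rtx_vial$family <- "beta"    # beta is not for costs
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_parameter_table(f), "Beta family")

  bad <- doc
  bad$utilities <- NULL                          # missing section
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_parameter_table(f), "lacks section")
})

test_that("unranged parameters receive the +/-20% sensitivity band", {
  pt <- base_params
  expect_equal(pt["transition.pd_to_hd", "low"], 0.1633 * 0.8)
  expect_equal(pt["transition.pd_to_hd", "high"], 0.1633 * 1.2)
  expect_identical(pt["transition.pd_to_hd", "family"], "fixed")
})

test_that("the registry exports and re-imports as flat CSV", {
  f <- tempfile(fileext = ".csv")
  export_parameter_table(base_params, f)
  back <- read.csv(f)
  expect_identical(nrow(back), nrow(base_params))
  expect_identical(names(back),
                   c("name", "mean", "low", "high", "family", "category",
                     "time_basis", "source"))
  expect_equal(back$mean[match("cost.rtx_vial", back$name)], 1366.2)
})

test_that("fit_parameter_distributions covers every row and preserves means", {
  fits <- fit_parameter_distributions(base_params)
  expect_identical(names(fits), base_params$name)
  means <- vapply(fits, function(f) f$mean, numeric(1))
  expect_equal(unname(means), base_params$mean, tolerance = 1e-9)
  fams <- vapply(fits, function(f) f$family, character(1))
  expect_identical(unname(fams[base_params$family == "fixed"]),
                   rep("fixed", sum(base_params$family == "fixed")))
})
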
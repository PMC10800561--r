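#' Run the deterministic base-case analysis and write its report
#'
#' Loads the parameter table, runs both arms over the horizon, and writes
#' the yearly cumulative discounted cost/QALY table (CSV) and the
#' incremental summary with the ICER and the willingness-to-pay decision
#' (JSON).
#'
#' @param config Path to a parameter YAML document, or a loaded
#'   `param_table`.
#' @param out_dir Output directory (created if missing).
#' @param horizon_years Horizon override; defaults to the settings value.
#' @param wtp Willingness-to-pay override; defaults to the settings value.
#' @return The `cea_result`, invisibly; files are written to `out_dir`.
#' @export
run_base_case <- function(config = default_parameter_file(), out_dir = ".",
                          horizon_years = NULL, wtp = NULL) {
  pt <- if (inherits(config, "param_table")) config
        else load_parameter_table(config)
  st <- model_settings(pt)
  if (is.null(wtp)) wtp <- st$wtp_per_qaly
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr_rtx <- run_cohort(strategy_rtx(pt), pt, horizon_years)
  tr_tac <- run_cohort(strategy_tac(pt), pt, horizon_years)
  res <- compare_strategies(tr_rtx, tr_tac, wtp)
  export_cea_result(res,
                    csv_path = file.path(out_dir, "base_case_yearly.csv"),
                    json_path = file.path(out_dir, "base_case_summary.json"))
  write_trace_csv(tr_rtx, file.path(out_dir, "trace_rtx.csv"))
  write_trace_csv(tr_tac, file.path(out_dir, "trace_tac.csv"))
  invisible(res)
}

#' Run the full analysis pipeline and write all artifacts
#'
#' Orchestrates every stage on one seed: clinical efficacy/safety
#' statistics on the deterministic fixture cohort, the deterministic
#' base case, the one-way (tornado) sensitivity analysis, and the
#' probabilistic sensitivity analysis with acceptability curves across
#' the yearly horizons, plus tornado/CE-plane/CEAC figures and a run
#' manifest listing every file written.
#'
#' @param config Path to a parameter YAML document, or a `param_table`.
#' @param out_dir Output directory.
#' @param psa_iterations Monte Carlo iterations for the PSA.
#' @param seed Integer seed for all sampling.
#' @param plots Write figure files (PDF).
#' @return The manifest list, invisibly.
#' @export
run_full_reproduction <- function(config = default_parameter_file(),
                                  out_dir = ".", psa_iterations = 1000L,
                                  seed = 1L, plots = TRUE) {
  pt <- if (inherits(config, "param_table")) config
        else load_parameter_table(config)
  st <- model_settings(pt)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(path) { files <<- c(files, path); path }

  # clinical statistics on the fixture cohort
  cohort <- fixture_cohort()
  write_cohort_csv(cohort, emit(file.path(out_dir, "fixture_cohort.csv")))
  tally <- classify_outcomes(cohort)
  utils::write.csv(efficacy_table(tally),
                   emit(file.path(out_dir, "efficacy_table.csv")),
                   row.names = FALSE)
  utils::write.csv(safety_summary(fixture_safety_cohort()),
                   emit(file.path(out_dir, "safety_table.csv")),
                   row.names = FALSE)

  # deterministic base case
  base <- run_base_case(pt, out_dir)
  files <- c(files, file.path(out_dir, c("base_case_yearly.csv",
                                         "base_case_summary.json",
                                         "trace_rtx.csv", "trace_tac.csv")))

  # sensitivity analyses
  tornado <- one_way_dsa(pt)
  utils::write.csv(as.data.frame(tornado),
                   emit(file.path(out_dir, "tornado.csv")), row.names = FALSE)
  psa <- run_psa(pt, iterations = psa_iterations, seed = seed)
  utils::write.csv(psa$samples, emit(file.path(out_dir, "psa_samples.csv")),
                   row.names = FALSE)
  utils::write.csv(psa$ceac, emit(file.path(out_dir, "ceac.csv")),
                   row.names = FALSE)

  if (plots) {
    save_plot <- function(p, name, width = 7, height = 5) {
      path <- emit(file.path(out_dir, name))
      grDevices::pdf(path, width = width, height = height)
      print(p)
      grDevices::dev.off()
      path
    }
    save_plot(plot_tornado(tornado), "tornado.pdf")
    save_plot(plot_ce_plane(psa$samples, psa$wtp), "ce_plane.pdf", width = 9)
    save_plot(plot_ceac(psa$ceac), "ceac.pdf")
  }

  manifest <- list(
    command = "run_full_reproduction",
    package_version = as.character(utils::packageVersion("pmncea")),
    config_digest = if (is.character(config)) {
      unname(tools::md5sum(config))
    } else "in-memory param_table",
    seed = seed,
    psa_iterations = psa_iterations,
    psa_rejected = psa$rejected,
    settings = st,
    base_case = list(delta_cost = base$delta_cost,
                     delta_qaly = base$delta_qaly,
                     icer = base$icer, dominance = base$dominance,
                     cost_effective = base$cost_effective),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = files)
  jsonlite::write_json(manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("outputs listed in manifest are missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}
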
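# Reporting commands: each writes CSV/JSON artifacts plus a run manifest
# and returns the emitted paths. These (plus the thin Rscript under
# inst/cli/) are the package's command-style interface.

write_manifest <- function(out_dir, ps, seed, files) {
  snapshot <- unclass(ps)
  snapshot$esrd_costs <- unclass(snapshot$esrd_costs)
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("nephroCEA")),
    seed = seed,
    config = snapshot,
    files = files
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, path)
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

msg <- function(quiet, ...) if (!quiet) message(...)

#' Base-case report
#'
#' Evaluates the three strategies under a configuration (packaged base case
#' when `config` is `NULL`), writes the per-strategy results, the
#' incremental comparison with dominance labels, one cohort-trace CSV per
#' strategy, and a manifest sufficient to reproduce the run.
#'
#' @param config Path to a YAML config, a named list, or `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the emitted file paths.
#' @export
report_base_case <- function(config = NULL, out_dir = ".", quiet = FALSE) {
  ps <- load_parameters(config)
  dem <- default_demography(ps)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg(quiet, "base case: ages ", ps$age_entry, "-", ps$age_end,
      ", drug cost ", ps$c_drug_mixed, " euros/yr")
  results <- evaluate_strategies(ps, dem)
  cmp <- compare_strategies(results)
  files <- write_csv_(results, file.path(out_dir, "strategy_results.csv"))
  files <- c(files, write_csv_(cmp$table,
                               file.path(out_dir, "incremental.csv")))
  for (s in results$strategy) {
    tr <- run_cohort(s, ps, dem$life_table)
    files <- c(files, write_csv_(as.data.frame(tr),
                                 file.path(out_dir, paste0("trace_", s, ".csv"))))
  }
  files <- write_manifest(out_dir, ps, seed = NA, files)
  invisible(files)
}

#' Sensitivity-analysis report
#'
#' Writes the one-way sensitivity table (one row per parameter and bound)
#' and the breakeven annual drug cost.
#'
#' @inheritParams report_base_case
#' @return Invisibly, the emitted file paths.
#' @export
report_sensitivity <- function(config = NULL, out_dir = ".", quiet = FALSE) {
  ps <- load_parameters(config)
  dem <- default_demography(ps)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sa <- univariate_sa(ps, demography = dem)
  files <- write_csv_(sa, file.path(out_dir, "univariate_sa.csv"))
  thr <- threshold_drug_cost(ps, dem)
  msg(quiet, sprintf("breakeven annual drug cost: %.2f euros", thr))
  thr_path <- file.path(out_dir, "threshold.json")
  jsonlite::write_json(list(breakeven_drug_cost = thr,
                            base_drug_cost = ps$c_drug_mixed),
                       thr_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, thr_path)
  files <- write_manifest(out_dir, ps, seed = NA, files)
  invisible(files)
}

#' Probabilistic-sensitivity-analysis report
#'
#' Runs the Monte Carlo analysis and writes the acceptability curve, the
#' cost-effectiveness-plane scatter (one row per draw) and a summary JSON
#' with the probability of savings and the mean incremental cost/QALYs.
#'
#' @inheritParams report_base_case
#' @param n_draws Number of replications (default 1000).
#' @param seed RNG seed (default 20110, recorded in the manifest).
#' @param wtp_max,wtp_step Willingness-to-pay grid for the acceptability
#'   curve (euros/QALY).
#' @return Invisibly, the emitted file paths.
#' @export
report_psa <- function(config = NULL, out_dir = ".", n_draws = 1000,
                       seed = 20110, wtp_max = 100000, wtp_step = 1000,
                       quiet = FALSE) {
  ps <- load_parameters(config)
  dem <- default_demography(ps)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- run_psa(ps, demography = dem, n_draws = n_draws, seed = seed)
  curve <- ceac(samples, seq(0, wtp_max, by = wtp_step))
  files <- write_csv_(curve, file.path(out_dir, "ceac.csv"))
  files <- c(files, write_csv_(
    samples[, c("draw", "delta_cost", "delta_qalys")],
    file.path(out_dir, "scatter.csv")))
  summ <- psa_summary(samples)
  msg(quiet, sprintf("probability of savings: %.1f%%",
                     100 * summ$probability_of_savings))
  sum_path <- file.path(out_dir, "psa_summary.json")
  jsonlite::write_json(summ, sum_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, sum_path)
  files <- write_manifest(out_dir, ps, seed = seed, files)
  invisible(files)
}
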
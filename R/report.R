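# Reporting commands: each runs one stage end to end, writes its numeric
# outputs as CSV/JSON under out_dir, and returns a manifest of what was
# written. These back the thin command-line wrapper in inst/scripts.

write_manifest <- function(out_dir, scenario_id, seed, files) {
  man <- list(scenario = scenario_id,
              package_version = as.character(utils::packageVersion("markovcea")),
              seed = seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing)) stop("outputs not written: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  man$manifest_path <- path
  invisible(man)
}

resolve_scenario <- function(scenario) {
  if (inherits(scenario, "cea_scenario")) return(scenario)
  if (is.character(scenario) && file.exists(scenario))
    return(load_scenario(scenario))
  if (is.character(scenario)) return(builtin_scenarios(scenario))
  validate_scenario(scenario)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  out_dir
}

#' Run the base case and write all result files
#'
#' Writes the per-arm results table, the incremental comparison, both
#' cohort traces, both cost breakdowns, a parameter audit listing and a run
#' manifest.
#'
#' @param scenario A `cea_scenario`, a bundled scenario name or a scenario
#'   file path.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
cmd_base_case <- function(scenario, out_dir) {
  scenario <- resolve_scenario(scenario)
  ensure_dir(out_dir)
  run <- run_cea(scenario)
  files <- character(0)
  utils::write.csv(results_table(run), file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  files <- c(files, "results.csv")
  cmp <- run$comparison
  jsonlite::write_json(
    list(delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
         delta_ly = cmp$delta_ly, icer_per_qaly = cmp$icer_per_qaly,
         icer_per_ly = cmp$icer_per_ly, dominance = cmp$dominance,
         nmb_at_wtp = nmb(cmp, scenario$settings$wtp),
         wtp = scenario$settings$wtp),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files <- c(files, "comparison.json")
  for (role in c("intervention", "comparator")) {
    tf <- paste0("trace_", role, ".csv")
    write_trace(run$traces[[role]], file.path(out_dir, tf))
    cf <- paste0("costs_", role, ".csv")
    write_costs(cycle_costs(scenario, role, run$traces[[role]]),
                file.path(out_dir, cf))
    files <- c(files, tf, cf)
  }
  utils::write.csv(parameter_table(scenario),
                   file.path(out_dir, "parameters.csv"), row.names = FALSE)
  files <- c(files, "parameters.csv")
  write_manifest(out_dir, scenario$population, NA, files)
}

#' Fit a Weibull curve to a digitized KM file and write the result
#'
#' @param km_file Delimited text file readable by [read_km()].
#' @param out_dir Output directory.
#' @param method Passed to [fit_weibull()].
#' @return The manifest, invisibly.
#' @export
cmd_fit <- function(km_file, out_dir,
                    method = c("transform_ols", "interval_weighted")) {
  method <- match.arg(method)
  ensure_dir(out_dir)
  fit <- fit_weibull(read_km(km_file), method)
  jsonlite::write_json(
    list(shape = fit$params$shape, scale = fit$params$scale, rss = fit$rss,
         n_points_used = fit$n_points_used, method = fit$method),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, km_file, NA, "fit.json")
}

#' Tornado analysis command
#'
#' @inheritParams cmd_base_case
#' @return The manifest, invisibly.
#' @export
cmd_tornado <- function(scenario, out_dir) {
  scenario <- resolve_scenario(scenario)
  ensure_dir(out_dir)
  tor <- tornado(scenario)
  utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  jsonlite::write_json(list(baseline_icer = attr(tor, "baseline_icer")),
                       file.path(out_dir, "tornado_baseline.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, scenario$population, NA,
                 c("tornado.csv", "tornado_baseline.json"))
}

#' Probabilistic sensitivity analysis command
#'
#' @inheritParams cmd_base_case
#' @param n_draws Monte-Carlo draws.
#' @param seed Integer seed.
#' @param wtp_grid Thresholds for the acceptability curve.
#' @return The manifest, invisibly.
#' @export
cmd_psa <- function(scenario, out_dir, n_draws = 1000, seed = 1,
                    wtp_grid = seq(0, 300000, by = 10000)) {
  scenario <- resolve_scenario(scenario)
  ensure_dir(out_dir)
  samples <- run_psa(scenario, n_draws, seed)
  utils::write.csv(as.data.frame(samples), file.path(out_dir, "psa.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ceac(samples, wtp_grid)),
                   file.path(out_dir, "ceac.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(prob_ce_at_wtp = prob_cost_effective(samples,
                                              scenario$settings$wtp),
         wtp = scenario$settings$wtp, n_draws = n_draws, seed = seed),
    file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, scenario$population, seed,
                 c("psa.csv", "ceac.csv", "psa_summary.json"))
}

#' Threshold-price command
#'
#' Computes the fractional price reduction bringing the ICER to the
#' willingness-to-pay threshold for each intervention drug component.
#'
#' @inheritParams cmd_base_case
#' @param drugs Price-table entries to analyse; defaults to the
#'   intervention arm's treatment components.
#' @param wtp Threshold (defaults to the scenario's).
#' @return The manifest, invisibly.
#' @export
cmd_threshold <- function(scenario, out_dir, drugs = NULL,
                          wtp = NULL) {
  scenario <- resolve_scenario(scenario)
  ensure_dir(out_dir)
  if (is.null(wtp)) wtp <- scenario$settings$wtp
  if (is.null(drugs)) drugs <- unlist(scenario$intervention$treatment$components)
  res <- lapply(drugs, function(d)
    list(drug = d, reduction = threshold_price(scenario, d, wtp), wtp = wtp))
  names(res) <- drugs
  jsonlite::write_json(res, file.path(out_dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, scenario$population, NA, "threshold.json")
}
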
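#' @name scenario
#' @title Scenario objects
#'
#' @description A scenario bundles every input of one population comparison:
#' Weibull survival parameters for both arms and endpoints, utilities, the
#' drug price table, adverse-event profiles, subsequent-therapy mixes, model
#' settings and the one-way/PSA ranges. Scenarios are plain lists of class
#' `cea_scenario`, serialised as YAML (or JSON); three fixtures covering the
#' PD-L1 >= 50%, >= 1% and < 1% populations ship with the package.
NULL

.settings_defaults <- list(
  cycle_length_days = 42,
  horizon_years = 20,
  annual_discount_rate = 0.03,
  wtp = 150000,
  half_cycle_correction = FALSE,
  ae_accrual = "per_cycle",          # or "one_time"
  apply_discontinuation = FALSE,
  ct_interval_pfs_weeks = 6,
  ct_interval_pd_weeks = 9
)

.scenario_keys <- c("population", "settings", "prices", "ae_costs",
                    "other_costs", "utilities", "reference_patient",
                    "intervention", "comparator", "sa_ranges")
.arm_keys <- c("name", "pfs", "os", "treatment", "discontinuation",
               "ae", "subsequent")
.utility_keys <- c("pfs_intervention", "pfs_comparator", "pd")
.other_cost_keys <- c("administration", "ct_scan", "laboratory")

#' Model settings constructor
#'
#' Fills unspecified fields with the base-case defaults: 6-week (42-day)
#' cycles, 20-year horizon, 3% annual discount rate applied to both costs and
#' outcomes, willingness-to-pay 150000 USD/QALY, no half-cycle correction,
#' per-cycle adverse-event accrual, and CT imaging every 6 weeks in PFS /
#' every 9 weeks in PD.
#'
#' @param ... Named settings overriding the defaults.
#' @return A list of class `model_settings`.
#' @export
model_settings <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.settings_defaults))
  if (length(bad)) stop("unknown settings: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  s <- utils::modifyList(.settings_defaults, over)
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], as.numeric)  # JSON round-trips may give integers
  if (s$cycle_length_days <= 0) stop("cycle_length_days must be positive",
                                     call. = FALSE)
  if (s$horizon_years <= 0) stop("horizon_years must be positive", call. = FALSE)
  if (s$annual_discount_rate < 0) stop("annual_discount_rate must be >= 0",
                                       call. = FALSE)
  if (s$wtp <= 0) stop("wtp must be positive", call. = FALSE)
  if (floor(s$horizon_years * 365.25 / s$cycle_length_days) < 1)
    stop("horizon must cover at least one cycle", call. = FALSE)
  if (!s$ae_accrual %in% c("per_cycle", "one_time"))
    stop("ae_accrual must be 'per_cycle' or 'one_time'", call. = FALSE)
  class(s) <- "model_settings"
  s
}

#' Number of cycles in the cohort trace implied by the settings
#' @param settings A [model_settings()] object.
#' @return Integer trace length (cycle 0 .. horizon).
#' @export
n_cycles <- function(settings) {
  as.integer(floor(settings$horizon_years * 365.25 / settings$cycle_length_days)) + 1L
}

fail <- function(...) stop(..., call. = FALSE)

check_number <- function(x, what, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fail(what, " must be a single finite number")
  if (x < lo || x > hi)
    fail(what, " = ", x, " outside [", lo, ", ", hi, "]")
  invisible(x)
}

validate_arm <- function(arm, role, scenario) {
  bad <- setdiff(names(arm), .arm_keys)
  if (length(bad)) fail(role, ": unknown keys: ", paste(bad, collapse = ", "))
  for (ep in c("pfs", "os")) {
    if (is.null(arm[[ep]])) fail(role, ": missing ", ep, " Weibull parameters")
    as_weibull_params(arm[[ep]])
  }
  if (!is.null(arm$discontinuation))
    check_number(arm$discontinuation, paste0(role, " discontinuation"), 0, 1)
  trt <- arm$treatment
  if (is.null(trt$type) || !trt$type %in% c("components", "doublet"))
    fail(role, ": treatment$type must be 'components' or 'doublet'")
  if (trt$type == "components") {
    miss <- setdiff(unlist(trt$components), names(scenario$prices))
    if (length(miss)) fail(role, ": treatment components without a price: ",
                           paste(miss, collapse = ", "))
    if (!is.null(trt$max_cycles))
      check_number(trt$max_cycles, paste0(role, " max_cycles"), 0)
  } else {
    check_number(trt$nonsquamous, paste0(role, " nonsquamous share"), 0, 1)
    cs <- if (is.null(trt$carboplatin_share)) 0.5 else trt$carboplatin_share
    check_number(cs, paste0(role, " carboplatin_share"), 0, 1)
    for (nm in c("pemetrexed", "gemcitabine", "carboplatin", "cisplatin"))
      if (is.null(scenario$prices[[nm]]))
        fail(role, ": doublet treatment requires a price for ", nm)
  }
  for (ae in arm$ae) {
    if (is.null(ae$name)) fail(role, ": adverse event without a name")
    check_number(ae$risk, paste0(role, " adverse event '", ae$name, "' risk"),
                 0, 1)
    if (is.null(scenario$ae_costs[[ae$name]]))
      fail(role, ": no unit cost for adverse event '", ae$name, "'")
  }
  tot <- 0
  for (sx in arm$subsequent) {
    if (is.null(sx$therapy)) fail(role, ": subsequent item without a therapy")
    check_number(sx$proportion,
                 paste0(role, " subsequent '", sx$therapy, "' proportion"), 0, 1)
    if (is.null(scenario$prices[[sx$therapy]]))
      fail(role, ": no price for subsequent therapy '", sx$therapy, "'")
    if (!is.null(sx$accrual) && !sx$accrual %in% c("per_cycle", "one_time"))
      fail(role, ": subsequent accrual must be 'per_cycle' or 'one_time'")
    tot <- tot + sx$proportion
  }
  if (tot > 1 + 1e-9)
    fail(role, ": subsequent therapy proportions sum to ", round(tot, 4), " > 1")
  invisible(arm)
}

#' Validate a scenario
#'
#' Checks every structural invariant: known keys only, positive Weibull
#' parameters, risks and utilities in \[0,1\], non-negative costs, subsequent
#' therapy proportions summing to at most one per arm, resolvable
#' sensitivity-range paths, and valid settings. Called by [load_scenario()]
#' and by all pipeline entry points.
#'
#' @param scenario A scenario list.
#' @return The scenario, invisibly, with settings defaults filled in.
#' @export
validate_scenario <- function(scenario) {
  bad <- setdiff(names(scenario), .scenario_keys)
  if (length(bad)) fail("unknown scenario keys: ", paste(bad, collapse = ", "))
  for (k in c("population", "prices", "ae_costs", "other_costs", "utilities",
              "intervention", "comparator"))
    if (is.null(scenario[[k]])) fail("scenario is missing '", k, "'")
  scenario$settings <- do.call(model_settings, as.list(scenario$settings))
  for (nm in names(scenario$prices))
    check_number(scenario$prices[[nm]], paste0("price '", nm, "'"), 0)
  for (nm in names(scenario$ae_costs))
    check_number(scenario$ae_costs[[nm]], paste0("AE cost '", nm, "'"), 0)
  bad <- setdiff(names(scenario$other_costs), .other_cost_keys)
  if (length(bad)) fail("unknown other_costs keys: ", paste(bad, collapse = ", "))
  for (nm in .other_cost_keys)
    check_number(scenario$other_costs[[nm]], paste0("other cost '", nm, "'"), 0)
  bad <- setdiff(names(scenario$utilities), .utility_keys)
  if (length(bad)) fail("unknown utilities keys: ", paste(bad, collapse = ", "))
  for (nm in .utility_keys)
    check_number(scenario$utilities[[nm]], paste0("utility '", nm, "'"), 0, 1)
  validate_arm(scenario$intervention, "intervention", scenario)
  validate_arm(scenario$comparator, "comparator", scenario)
  for (r in scenario$sa_ranges) {
    get_param(scenario, r$path)  # errors if unresolvable
    if (r$min > r$max)
      fail("sa_ranges entry '", r$path, "': min exceeds max")
    if (!r$dist %in% c("beta", "gamma"))
      fail("sa_ranges entry '", r$path, "': dist must be 'beta' or 'gamma'")
  }
  class(scenario) <- "cea_scenario"
  invisible(scenario)
}

#' Load a scenario file
#'
#' Reads and validates a YAML (`.yaml`/`.yml`) or JSON (`.json`) scenario
#' file. Missing optional settings are filled with documented defaults;
#' unknown keys are rejected.
#'
#' @param path Path to the scenario file.
#' @return A validated `cea_scenario`.
#' @seealso [builtin_scenarios()], [write_scenario()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) fail("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) fail("cannot parse ", path, ": ",
                                      conditionMessage(e)))
  }
  validate_scenario(raw)
}

#' Write a scenario file
#'
#' Serialisation is lossless to full numeric precision; a written scenario
#' reloads identically.
#'
#' @param scenario A `cea_scenario`.
#' @param path Destination path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  scenario <- validate_scenario(scenario)
  x <- unclass(scenario)
  x$settings <- unclass(x$settings)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Bundled population scenarios
#'
#' The three first-line advanced NSCLC populations stratified by tumour
#' PD-L1 expression: `pdl1_ge50` (>= 50%), `pdl1_ge1` (>= 1%) and `pdl1_lt1`
#' (< 1%). The >= 50% and >= 1% populations share the 70.8/29.2
#' non-squamous/squamous histology split and adverse-event profiles; the
#' < 1% population uses 75.3/24.7 and its own profiles.
#'
#' @param name Optional scenario name; if omitted all three are returned as a
#'   named list.
#' @return A `cea_scenario`, or a named list of all three.
#' @export
builtin_scenarios <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "markovcea")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  all <- lapply(files, load_scenario)
  names(all) <- vapply(all, function(s) s$population, "")
  all <- all[c("pdl1_ge50", "pdl1_ge1", "pdl1_lt1")]
  if (is.null(name)) return(all)
  if (!name %in% names(all))
    fail("unknown builtin scenario '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  all[[name]]
}

#' Flat audit listing of every scenario parameter
#'
#' Enumerates each numeric input as a (path, value) pair, suitable for CSV
#' export and for checking the scenario against its source table.
#'
#' @param scenario A `cea_scenario`.
#' @return A data frame with columns `path` and `value`.
#' @export
parameter_table <- function(scenario) {
  scenario <- validate_scenario(scenario)
  rows <- list()
  add <- function(path, value) rows[[length(rows) + 1L]] <<-
    data.frame(path = path, value = as.numeric(value))
  for (role in c("intervention", "comparator")) {
    arm <- scenario[[role]]
    for (ep in c("pfs", "os")) {
      add(paste(role, ep, "shape", sep = "."), arm[[ep]]$shape)
      add(paste(role, ep, "scale", sep = "."), arm[[ep]]$scale)
    }
    if (!is.null(arm$discontinuation))
      add(paste0(role, ".discontinuation"), arm$discontinuation)
    if (identical(arm$treatment$type, "doublet"))
      add(paste0(role, ".nonsquamous"), arm$treatment$nonsquamous)
    for (ae in arm$ae) add(paste0(role, ".ae.", ae$name), ae$risk)
    for (sx in arm$subsequent)
      add(paste0(role, ".subsequent.", sx$therapy), sx$proportion)
  }
  for (nm in .utility_keys) add(paste0("utilities.", nm),
                                scenario$utilities[[nm]])
  for (nm in names(scenario$prices)) add(paste0("prices.", nm),
                                         scenario$prices[[nm]])
  for (nm in names(scenario$ae_costs)) add(paste0("ae_costs.", nm),
                                           scenario$ae_costs[[nm]])
  for (nm in .other_cost_keys) add(paste0("other_costs.", nm),
                                   scenario$other_costs[[nm]])
  for (nm in names(scenario$reference_patient))
    add(paste0("reference_patient.", nm), scenario$reference_patient[[nm]])
  add("settings.annual_discount_rate", scenario$settings$annual_discount_rate)
  do.call(rbind, rows)
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("CEA scenario '%s': %s vs %s\n", x$population,
              x$intervention$name, x$comparator$name))
  cat(sprintf("  %d cycles of %g days, discount %.1f%%/yr, WTP $%s/QALY\n",
              n_cycles(x$settings), x$settings$cycle_length_days,
              100 * x$settings$annual_discount_rate,
              format(x$settings$wtp, big.mark = ",")))
  invisible(x)
}
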
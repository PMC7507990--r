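#' Accumulate discounted outcomes for one arm
#'
#' Life-years are the alive-state occupancy summed over cycles, converted to
#' years and discounted; QALYs weight the progression-free and progressed
#' occupancy by the arm-specific PFS utility and the shared PD utility;
#' costs sum the per-cycle flow components. Costs and outcomes share the
#' same discount factor.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param costs A `cost_breakdown` from [cycle_costs()].
#' @param utilities The scenario `utilities` list (`pfs_intervention`,
#'   `pfs_comparator`, `pd`).
#' @param arm_role `"intervention"` or `"comparator"` (selects the PFS
#'   utility).
#' @param settings A [model_settings()] object.
#' @return A list of class `arm_result` with discounted `total_cost`, `ly`,
#'   `qaly` and their undiscounted twins.
#' @export
accumulate <- function(trace, costs, utilities,
                       arm_role = c("intervention", "comparator"), settings) {
  arm_role <- match.arg(arm_role)
  settings <- do.call(model_settings, as.list(settings))
  nc <- n_cycles(settings)
  if (nrow(trace) != nc || nrow(costs) != nc)
    stop("trace/costs length does not match settings", call. = FALSE)
  cyl_years <- settings$cycle_length_days / 365.25
  d <- discount_factor(settings$annual_discount_rate, trace$cycle,
                       settings$cycle_length_days)
  occ <- occupancy_weights(trace, settings)
  alive <- occ[, "pfs"] + occ[, "pd"]
  u_pfs <- if (arm_role == "intervention") utilities$pfs_intervention else
    utilities$pfs_comparator
  uw <- u_pfs * occ[, "pfs"] + utilities$pd * occ[, "pd"]
  flow <- rowSums(as.data.frame(costs)[c("drug", "admin", "imaging", "lab",
                                         "ae", "subsequent")])
  res <- list(
    total_cost = sum(flow * d),
    ly = sum(alive * cyl_years * d),
    qaly = sum(uw * cyl_years * d),
    total_cost_undiscounted = sum(flow),
    ly_undiscounted = sum(alive * cyl_years),
    qaly_undiscounted = sum(uw * cyl_years),
    arm_role = arm_role)
  class(res) <- "arm_result"
  res
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm: cost $%.2f, %.3f LY, %.3f QALY (discounted)\n",
              x$arm_role, x$total_cost, x$ly, x$qaly))
  invisible(x)
}

#' Incremental comparison of two arms
#'
#' Deltas are intervention minus comparator. The ICER is reported only when
#' the incremental effect is non-zero and neither arm dominates; dominance
#' (one arm cheaper and more effective) is flagged instead of returning a
#' signed infinity or a misleading negative ratio.
#'
#' @param intervention,comparator `arm_result` objects computed under
#'   identical settings.
#' @return A list of class `cea_result` with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_per_qaly`, `icer_per_ly` (each `NA` when undefined)
#'   and a `dominance` flag (`"none"`, `"intervention_dominant"`,
#'   `"intervention_dominated"`).
#' @export
compare <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qaly - comparator$qaly
  dl <- intervention$ly - comparator$ly
  dominance <- if (dc <= 0 && dq >= 0 && (dc < 0 || dq > 0)) {
    "intervention_dominant"
  } else if (dc >= 0 && dq <= 0 && (dc > 0 || dq < 0)) {
    "intervention_dominated"
  } else "none"
  icer_q <- if (dominance == "none" && dq != 0) dc / dq else NA_real_
  icer_l <- if (dominance == "none" && dl != 0) dc / dl else NA_real_
  res <- list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
              icer_per_qaly = icer_q, icer_per_ly = icer_l,
              dominance = dominance)
  class(res) <- "cea_result"
  res
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("incremental: cost $%.2f, %.3f QALY, %.3f LY\n",
              x$delta_cost, x$delta_qaly, x$delta_ly))
  if (x$dominance != "none") {
    cat("dominance:", x$dominance, "\n")
  } else {
    cat(sprintf("ICER: $%.2f/QALY, $%.2f/LY\n", x$icer_per_qaly, x$icer_per_ly))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp x delta_qaly - delta_cost`; the intervention is preferred at the
#' willingness-to-pay threshold when positive.
#'
#' @param cea A `cea_result`.
#' @param wtp Willingness-to-pay threshold in USD per QALY (>= 0).
#' @return NMB in USD.
#' @export
nmb <- function(cea, wtp) {
  if (wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  wtp * cea$delta_qaly - cea$delta_cost
}

#' Run the full cost-effectiveness pipeline for a scenario
#'
#' Cohort simulation, costing and accumulation for both arms, then the
#' incremental comparison — the single entry point used by the reporting
#' commands and the sensitivity analyses.
#'
#' @param scenario A `cea_scenario`.
#' @return A list of class `cea_run` with elements `intervention`,
#'   `comparator` (both `arm_result`), `comparison` (`cea_result`) and
#'   `traces` (per-arm `cohort_trace`).
#' @export
run_cea <- function(scenario) {
  scenario <- validate_scenario(scenario)
  settings <- scenario$settings
  arms <- list()
  traces <- list()
  for (role in c("intervention", "comparator")) {
    trace <- run_cohort(scenario[[role]], settings)
    costs <- cycle_costs(scenario, role, trace, settings)
    arms[[role]] <- accumulate(trace, costs, scenario$utilities, role, settings)
    traces[[role]] <- trace
  }
  res <- list(intervention = arms$intervention,
              comparator = arms$comparator,
              comparison = compare(arms$intervention, arms$comparator),
              traces = traces,
              population = scenario$population,
              wtp = settings$wtp)
  class(res) <- "cea_run"
  res
}

#' @export
print.cea_run <- function(x, ...) {
  cat(sprintf("Base-case results, population '%s'\n", x$population))
  print(x$intervention); print(x$comparator); print(x$comparison)
  b <- nmb(x$comparison, x$wtp)
  cat(sprintf("NMB at WTP $%s/QALY: $%.2f (%scost-effective)\n",
              format(x$wtp, big.mark = ","), b, if (b > 0) "" else "not "))
  invisible(x)
}

#' Tabulate base-case results
#'
#' One row per arm with discounted totals plus the incremental ratios,
#' mirroring the usual results-table layout of published cost-effectiveness
#' analyses.
#'
#' @param run A `cea_run` from [run_cea()].
#' @return A data frame with columns `strategy`, `total_cost`, `ly`, `qaly`,
#'   `icer_per_ly`, `icer_per_qaly`.
#' @export
results_table <- function(run) {
  data.frame(
    strategy = c("intervention", "comparator"),
    total_cost = c(run$intervention$total_cost, run$comparator$total_cost),
    ly = c(run$intervention$ly, run$comparator$ly),
    qaly = c(run$intervention$qaly, run$comparator$qaly),
    icer_per_ly = c(run$comparison$icer_per_ly, NA),
    icer_per_qaly = c(run$comparison$icer_per_qaly, NA))
}
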
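#' One-off adverse-event burden of a toxicity profile
#'
#' Sum over grade >= 3 events of per-patient incidence times the cost of
#' managing one event: \eqn{\sum_i \mathrm{risk}_i \times \mathrm{cost}_i}.
#' Under the default settings this burden accrues per treatment cycle while
#' in the progression-free state; with `ae_accrual = "one_time"` it is
#' charged once at model entry.
#'
#' @param profile A data frame with columns `risk` and `unit_cost` (one row
#'   per adverse event), e.g. from [arm_ae_profile()].
#' @return Burden in USD.
#' @export
ae_burden <- function(profile) {
  if (is.null(profile) || NROW(profile) == 0L) return(0)
  stopifnot(all(c("risk", "unit_cost") %in% names(profile)))
  if (any(profile$risk < 0 | profile$risk > 1))
    stop("adverse-event risks must lie in [0, 1]", call. = FALSE)
  if (any(profile$unit_cost < 0))
    stop("adverse-event unit costs must be >= 0", call. = FALSE)
  sum(profile$risk * profile$unit_cost)
}

#' Adverse-event profile of one arm with unit costs resolved
#'
#' @param scenario A `cea_scenario`.
#' @param role `"intervention"` or `"comparator"`.
#' @return A data frame with columns `name`, `risk`, `unit_cost`.
#' @export
arm_ae_profile <- function(scenario, role = c("intervention", "comparator")) {
  role <- match.arg(role)
  arm <- scenario[[role]]
  if (length(arm$ae) == 0L)
    return(data.frame(name = character(), risk = numeric(),
                      unit_cost = numeric()))
  data.frame(
    name = vapply(arm$ae, `[[`, "", "name"),
    risk = vapply(arm$ae, `[[`, 0, "risk"),
    unit_cost = vapply(arm$ae, function(a) scenario$ae_costs[[a$name]], 0))
}

#' Creatinine clearance by Cockcroft-Gault
#'
#' \eqn{(140 - \mathrm{age}) \times \mathrm{weight} / (72 \times
#' \mathrm{SCr})}, multiplied by 0.85 for females.
#'
#' @param age Age in years.
#' @param weight Body weight in kg.
#' @param serum_creatinine Serum creatinine in mg/dL.
#' @param sex `"male"` or `"female"`.
#' @return Creatinine clearance in mL/min.
#' @export
cockcroft_gault <- function(age, weight, serum_creatinine,
                            sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (age <= 0 || weight <= 0 || serum_creatinine <= 0)
    stop("age, weight and serum creatinine must be positive", call. = FALSE)
  crcl <- (140 - age) * weight / (72 * serum_creatinine)
  if (sex == "female") crcl <- 0.85 * crcl
  crcl
}

#' Carboplatin dose by the Calvert formula
#'
#' Dose (mg) = target AUC x (creatinine clearance + 25), with creatinine
#' clearance estimated by Cockcroft-Gault. A dosing audit helper: base-case
#' costing uses the per-cycle price table directly.
#'
#' @param target_auc Target area under the concentration-time curve
#'   (mg/mL/min).
#' @param age,weight,serum_creatinine,sex Passed to [cockcroft_gault()].
#' @return Dose in mg.
#' @export
carboplatin_dose <- function(target_auc, age = 65, weight = 70,
                             serum_creatinine = 1,
                             sex = c("male", "female")) {
  if (target_auc < 0) stop("target_auc must be >= 0", call. = FALSE)
  if (target_auc == 0) return(0)
  target_auc * (cockcroft_gault(age, weight, serum_creatinine, sex) + 25)
}

#' Body-surface-area based dose
#'
#' @param dose_per_m2 Dose intensity in mg per square metre.
#' @param bsa Body surface area in square metres.
#' @return Dose in mg.
#' @export
bsa_dose <- function(dose_per_m2, bsa) {
  if (dose_per_m2 < 0 || bsa <= 0)
    stop("dose_per_m2 must be >= 0 and bsa positive", call. = FALSE)
  dose_per_m2 * bsa
}

#' Per-cycle active-treatment drug cost schedule for one arm
#'
#' For a `components` treatment (the immunotherapy arm) the scheduled cost
#' is the sum of the component per-cycle prices, applied while in PFS up to
#' `max_cycles` (unlimited if unset). For a `doublet` treatment (the
#' chemotherapy arm) induction cycles cost the histology-weighted
#' platinum-doublet price — non-squamous patients on pemetrexed plus
#' platinum, squamous on gemcitabine plus platinum, with the platinum price
#' averaged over the carboplatin/cisplatin split — and later cycles cost
#' pemetrexed maintenance weighted by the non-squamous share. Table prices
#' are per 6-week model cycle, already covering all administrations within
#' the cycle.
#'
#' @param scenario A `cea_scenario`.
#' @param role `"intervention"` or `"comparator"`.
#' @param n_cycles Number of trace cycles.
#' @return Numeric vector of scheduled drug cost per cycle (USD), before
#'   multiplication by PFS occupancy.
#' @export
drug_schedule <- function(scenario, role, n_cycles) {
  arm <- scenario[[role]]
  trt <- arm$treatment
  prices <- scenario$prices
  t <- 0:(n_cycles - 1)
  if (identical(trt$type, "components")) {
    per <- sum(vapply(unlist(trt$components), function(nm) prices[[nm]], 0))
    sched <- rep(per, n_cycles)
    if (!is.null(trt$max_cycles)) sched[t >= trt$max_cycles] <- 0
  } else {
    cs <- if (is.null(trt$carboplatin_share)) 0.5 else trt$carboplatin_share
    platinum <- cs * prices$carboplatin + (1 - cs) * prices$cisplatin
    nonsq <- trt$nonsquamous
    induction <- nonsq * (prices$pemetrexed + platinum) +
      (1 - nonsq) * (prices$gemcitabine + platinum)
    ind_n <- if (is.null(trt$induction_cycles)) 2 else trt$induction_cycles
    maint <- if (is.null(trt$maintenance)) 0 else
      nonsq * prices[[trt$maintenance]]
    sched <- ifelse(t < ind_n, induction, maint)
  }
  if (isTRUE(scenario$settings$apply_discontinuation) &&
      !is.null(arm$discontinuation))
    sched <- sched * (1 - arm$discontinuation)
  sched
}

#' Per-cycle cost flows for one arm
#'
#' Turns a cohort trace into undiscounted per-cycle cost components:
#' \describe{
#'   \item{drug}{scheduled active-treatment cost x PFS occupancy.}
#'   \item{admin}{administration cost x PFS occupancy (active treatment
#'     only).}
#'   \item{imaging}{CT at the PFS surveillance interval x PFS occupancy,
#'     plus CT prorated to the longer post-progression interval x PD
#'     occupancy (231 x 6/9 per cycle under the defaults).}
#'   \item{lab}{laboratory cost x (PFS + PD) occupancy.}
#'   \item{ae}{adverse-event burden ([ae_burden()]) x PFS occupancy per
#'     cycle, or charged once at cycle 0 when
#'     `settings$ae_accrual == "one_time"`.}
#'   \item{subsequent}{per-cycle subsequent-therapy items
#'     (proportion x price) x PD occupancy; items marked
#'     `accrual: one_time` are charged on the newly progressing fraction
#'     instead.}
#' }
#'
#' @param scenario A `cea_scenario`.
#' @param role `"intervention"` or `"comparator"`.
#' @param trace A `cohort_trace` from [run_cohort()] under the same
#'   settings.
#' @param settings A [model_settings()] object; defaults to the scenario's.
#' @return A data frame of class `cost_breakdown` with columns `cycle`,
#'   `drug`, `admin`, `imaging`, `lab`, `ae`, `subsequent`; the attribute
#'   `one_time` lists lump components for audit.
#' @export
cycle_costs <- function(scenario, role, trace, settings = scenario$settings) {
  settings <- do.call(model_settings, as.list(settings))
  nc <- n_cycles(settings)
  if (nrow(trace) != nc)
    stop("trace has ", nrow(trace), " cycles but settings imply ", nc,
         call. = FALSE)
  arm <- scenario[[role]]
  occ <- occupancy_weights(trace, settings)
  pfs <- occ[, "pfs"]; pd <- occ[, "pd"]
  oc <- scenario$other_costs
  drug <- drug_schedule(scenario, role, nc) * pfs
  admin <- oc$administration * pfs
  ct_pd <- oc$ct_scan * settings$ct_interval_pfs_weeks /
    settings$ct_interval_pd_weeks
  imaging <- oc$ct_scan * pfs + ct_pd * pd
  lab <- oc$laboratory * (pfs + pd)
  burden <- ae_burden(arm_ae_profile(scenario, role))
  one_time <- numeric(0)
  if (identical(settings$ae_accrual, "one_time")) {
    ae <- c(burden, numeric(nc - 1))
    one_time["ae_burden"] <- burden
  } else {
    ae <- burden * pfs
  }
  subsequent <- numeric(nc)
  for (sx in arm$subsequent) {
    price <- scenario$prices[[sx$therapy]]
    if (identical(sx$accrual, "one_time")) {
      subsequent <- subsequent + sx$proportion * price * trace$entered_pd
      one_time[paste0("subsequent_", sx$therapy)] <- sx$proportion * price
    } else {
      subsequent <- subsequent + sx$proportion * price * pd
    }
  }
  out <- data.frame(cycle = trace$cycle, drug = drug, admin = admin,
                    imaging = imaging, lab = lab, ae = ae,
                    subsequent = subsequent)
  attr(out, "one_time") <- one_time
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Export a cost breakdown to CSV
#'
#' @param costs A `cost_breakdown`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_costs <- function(costs, path) {
  utils::write.csv(as.data.frame(costs), path, row.names = FALSE)
  invisible(path)
}
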
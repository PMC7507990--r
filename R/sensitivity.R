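#' Moment-matched sampling distribution from a (mean, min, max) range
#'
#' The range is treated as an approximate 95% interval, so
#' `sd = (max - min) / 3.92` (an alternative divisor, e.g. 4, can be
#' supplied). Beta parameters come from the method of moments
#' \eqn{\alpha = m[(m(1-m))/s^2 - 1]}, \eqn{\beta = \alpha(1-m)/m};
#' gamma uses \eqn{shape = m^2/s^2}, \eqn{rate = m/s^2}. A zero-width range
#' yields a degenerate (point-mass) spec.
#'
#' @param mean Baseline value (the distribution mean).
#' @param min,max Plausible range, `min <= mean <= max`.
#' @param family `"beta"` (values in \[0,1\]: utilities, risks) or
#'   `"gamma"` (non-negative: costs).
#' @param range_divisor Divisor converting the range width to a standard
#'   deviation (default 3.92).
#' @return A list of class `dist_spec` with the family and its parameters.
#' @export
dist_from_range <- function(mean, min, max, family = c("beta", "gamma"),
                            range_divisor = 3.92) {
  family <- match.arg(family)
  if (min > mean + 1e-12 || max < mean - 1e-12)
    stop("need min <= mean <= max", call. = FALSE)
  sd <- (max - min) / range_divisor
  if (sd == 0)
    return(structure(list(family = "degenerate", mean = mean, sd = 0),
                     class = "dist_spec"))
  if (family == "beta") {
    if (mean <= 0 || mean >= 1)
      stop("beta requires mean strictly inside (0, 1)", call. = FALSE)
    v <- sd^2
    if (v >= mean * (1 - mean))
      stop("range too wide for a beta distribution at this mean", call. = FALSE)
    alpha <- mean * (mean * (1 - mean) / v - 1)
    spec <- list(family = "beta", mean = mean, sd = sd,
                 shape1 = alpha, shape2 = alpha * (1 - mean) / mean)
  } else {
    if (mean <= 0) stop("gamma requires a positive mean", call. = FALSE)
    spec <- list(family = "gamma", mean = mean, sd = sd,
                 shape = mean^2 / sd^2, rate = mean / sd^2)
  }
  structure(spec, class = "dist_spec")
}

#' Draw from a `dist_spec`
#'
#' @param spec A [dist_from_range()] spec.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  switch(spec$family,
         degenerate = rep(spec$mean, n),
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate))
}

sa_range_for <- function(scenario, path) {
  for (r in scenario$sa_ranges) if (identical(r$path, path)) return(r)
  NULL
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Reruns the full pipeline with the parameter set to its lower and upper
#' bound (all other inputs at baseline) and reports both ICERs and the span
#' between them. When a bound makes the intervention dominant/dominated the
#' corresponding ICER is `NA` and the span falls back to the defined values.
#'
#' @param scenario A `cea_scenario`.
#' @param parameter_path A parameter path (see [get_param()]).
#' @param bounds Optional `c(min, max)`; defaults to the scenario's
#'   `sa_ranges` entry for the path.
#' @return A one-row data frame: `parameter_path`, `icer_at_min`,
#'   `icer_at_max`, `span`.
#' @export
one_way <- function(scenario, parameter_path, bounds = NULL) {
  scenario <- validate_scenario(scenario)
  if (is.null(bounds)) {
    r <- sa_range_for(scenario, parameter_path)
    if (is.null(r)) stop("no sa_ranges entry for '", parameter_path,
                         "' and no bounds given", call. = FALSE)
    bounds <- c(r$min, r$max)
  }
  icers <- vapply(bounds, function(v) {
    run <- run_cea(set_param(scenario, parameter_path, v))
    run$comparison$icer_per_qaly
  }, 0)
  span <- if (all(is.finite(icers))) abs(icers[2] - icers[1]) else NA_real_
  data.frame(parameter_path = parameter_path,
             icer_at_min = icers[1], icer_at_max = icers[2], span = span)
}

#' Tornado analysis over every ranged parameter
#'
#' Runs [one_way()] for each `sa_ranges` entry and ranks parameters by the
#' width of their ICER span.
#'
#' @param scenario A `cea_scenario`.
#' @return A data frame (one row per parameter, sorted by decreasing span)
#'   with attribute `baseline_icer`.
#' @export
tornado <- function(scenario) {
  scenario <- validate_scenario(scenario)
  if (length(scenario$sa_ranges) == 0L)
    stop("scenario has no sa_ranges", call. = FALSE)
  rows <- lapply(scenario$sa_ranges,
                 function(r) one_way(scenario, r$path, c(r$min, r$max)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "baseline_icer") <- run_cea(scenario)$comparison$icer_per_qaly
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every `sa_ranges` parameter independently from its moment-matched
#' distribution (beta for utilities and risks, gamma for costs), reruns the
#' pipeline per draw, and records the incremental outcome. Reproducible for
#' a given seed; all draws are generated up front from a single seeded
#' stream.
#'
#' @param scenario A `cea_scenario`.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed.
#' @param range_divisor Passed to [dist_from_range()].
#' @return A data frame of class `psa_samples` with one row per draw:
#'   `draw`, `delta_cost`, `delta_qaly`, `delta_ly`, `icer_per_qaly`,
#'   `dominance`. The matrix of drawn parameter values is attached as
#'   attribute `draws`.
#' @export
run_psa <- function(scenario, n_draws = 1000, seed = 1, range_divisor = 3.92) {
  scenario <- validate_scenario(scenario)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  paths <- vapply(scenario$sa_ranges, `[[`, "", "path")
  if (length(paths) == 0L) stop("scenario has no sa_ranges", call. = FALSE)
  specs <- lapply(scenario$sa_ranges, function(r)
    dist_from_range(get_param(scenario, r$path), r$min, r$max, r$dist,
                    range_divisor))
  set.seed(seed)
  draws <- vapply(specs, sample_dist, numeric(n_draws), n = n_draws)
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- paths
  res <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    sc <- scenario
    for (j in seq_along(paths)) sc <- set_param(sc, paths[j], draws[i, j])
    cmp <- run_cea(sc)$comparison
    res[[i]] <- data.frame(draw = i, delta_cost = cmp$delta_cost,
                           delta_qaly = cmp$delta_qaly,
                           delta_ly = cmp$delta_ly,
                           icer_per_qaly = cmp$icer_per_qaly,
                           dominance = cmp$dominance)
  }
  out <- do.call(rbind, res)
  attr(out, "draws") <- draws
  class(out) <- c("psa_samples", "data.frame")
  out
}

#' Probability of cost-effectiveness from PSA draws
#'
#' Fraction of draws with positive net monetary benefit at a threshold.
#'
#' @param samples A `psa_samples` data frame.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return Probability in \[0, 1\].
#' @export
prob_cost_effective <- function(samples, wtp) {
  mean(wtp * samples$delta_qaly - samples$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param samples A `psa_samples` data frame from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay thresholds.
#' @return A data frame of class `ceac_curve` with columns `wtp` and
#'   `prob_ce`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 300000, by = 10000)) {
  if (NROW(samples) == 0L) stop("no PSA samples", call. = FALSE)
  out <- data.frame(wtp = wtp_grid,
                    prob_ce = vapply(wtp_grid, prob_cost_effective,
                                     0, samples = samples))
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Price reduction needed to reach a willingness-to-pay threshold
#'
#' Finds, by bisection, the smallest fractional reduction of one drug's
#' price-table entry at which the rerun ICER first drops to the threshold.
#' The reduction applies everywhere the drug enters the model — the
#' intervention acquisition schedule and any subsequent-therapy use in
#' either arm — as a price cut would. Dominant outcomes count as below the
#' threshold.
#'
#' @param scenario A `cea_scenario`.
#' @param drug Name of a price-table entry (e.g. `"nivolumab"`).
#' @param wtp Threshold in USD/QALY; defaults to the scenario's.
#' @param tol Bisection tolerance on the reduction fraction (default 0.001).
#' @return Fraction in \[0, 1\], 0 if already cost-effective, or `NA` with a
#'   message if a 100% reduction still leaves the ICER above the threshold.
#' @export
threshold_price <- function(scenario, drug, wtp = scenario$settings$wtp,
                            tol = 0.001) {
  scenario <- validate_scenario(scenario)
  base_price <- scenario$prices[[drug]]
  if (is.null(base_price)) stop("no price entry '", drug, "'", call. = FALSE)
  below <- function(r) {
    cmp <- run_cea(set_param(scenario, paste0("prices.", drug),
                             base_price * (1 - r)))$comparison
    cmp$dominance == "intervention_dominant" ||
      (!is.na(cmp$icer_per_qaly) && cmp$icer_per_qaly <= wtp)
  }
  if (below(0)) return(0)
  if (!below(1)) {
    message("ICER stays above the threshold even at a 100% price reduction")
    return(NA_real_)
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (below(mid)) hi <- mid else lo <- mid
  }
  hi
}
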
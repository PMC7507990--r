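#' Configuration for a synthetic digitized Kaplan-Meier series
#'
#' Describes a simulated trial read-out: event times drawn from a known
#' Weibull distribution, administrative censoring at a fixed cycle, the grid
#' of time points at which the curve is "digitized", and a small additive
#' noise mimicking manual curve extraction error.
#'
#' @param true_params A [weibull_params()] object generating event times.
#' @param n_patients Number of simulated patients (>= 1).
#' @param admin_censor_cycle Administrative censoring time in cycles (> 0).
#' @param grid Cycle times at which to report the curve; must lie within
#'   \[0, admin_censor_cycle\]. Defaults to every cycle up to censoring.
#' @param seed Integer seed.
#' @param digitization_noise_sd Standard deviation of additive noise on the
#'   survival fractions (must be < 0.05; default 0.005).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(true_params, n_patients, admin_censor_cycle,
                       grid = NULL, seed = 1, digitization_noise_sd = 0.005) {
  true_params <- as_weibull_params(true_params)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (admin_censor_cycle <= 0)
    stop("admin_censor_cycle must be positive (censoring everyone at entry ",
         "leaves nothing to fit)", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, floor(admin_censor_cycle))
  if (any(grid < 0) || any(grid > admin_censor_cycle))
    stop("grid points must lie within [0, admin_censor_cycle]", call. = FALSE)
  if (digitization_noise_sd < 0 || digitization_noise_sd >= 0.05)
    stop("digitization_noise_sd must be in [0, 0.05)", call. = FALSE)
  structure(list(true_params = true_params, n_patients = n_patients,
                 admin_censor_cycle = admin_censor_cycle, grid = sort(grid),
                 seed = seed, digitization_noise_sd = digitization_noise_sd),
            class = "sim_config")
}

#' Simulate a digitized Kaplan-Meier point series
#'
#' Draws event times by inverse-CDF sampling,
#' \eqn{T = (-\log U / \lambda)^{1/\gamma}}, applies administrative
#' censoring, computes the product-limit estimator, evaluates it on the
#' requested grid, and optionally adds digitization noise (clipped to
#' (0, 1\] and repaired to be non-increasing by a running minimum).
#'
#' @param config A [sim_config()] object.
#' @return A [km_series()] with `n_at_risk` counts at the grid times.
#' @export
simulate_km <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$true_params
  set.seed(config$seed)
  u <- stats::runif(config$n_patients)
  event_time <- (-log(u) / p$scale)^(1 / p$shape)
  cens <- config$admin_censor_cycle
  time <- pmin(event_time, cens)
  status <- as.integer(event_time <= cens)
  # product-limit estimator at the observed event times
  ord <- order(time)
  time <- time[ord]; status <- status[ord]
  n <- length(time)
  at_risk <- n - seq_len(n) + 1L
  km_step <- cumprod(1 - status / at_risk)
  ev <- status == 1L
  step_t <- time[ev]; step_s <- km_step[ev]
  surv_at <- function(tt) {
    idx <- findInterval(tt, step_t)
    ifelse(idx == 0L, 1, step_s[pmax(idx, 1L)])
  }
  grid <- config$grid
  s <- surv_at(grid)
  nrisk <- vapply(grid, function(g) sum(time >= g), 0L)
  if (config$digitization_noise_sd > 0) {
    s <- s + stats::rnorm(length(s), 0, config$digitization_noise_sd)
    s <- pmin(pmax(s, 1e-6), 1)
    s <- cummin(s)  # isotonic repair: digitized curves cannot increase
  }
  if (any(grid == 0)) s[grid == 0] <- 1
  keep <- s > 0
  km_series(grid[keep], s[keep], nrisk[keep])
}

#' Jittered copy of a bundled scenario
#'
#' Perturbs every ranged parameter of a bundled scenario uniformly within
#' its one-way range — a stress-test generator producing valid but
#' off-baseline scenarios. With `amount = 0` the fixture is returned
#' unchanged.
#'
#' @param perturb_seed Integer seed.
#' @param scenario A `cea_scenario` to jitter (default the PD-L1 >= 50%
#'   fixture).
#' @param amount Jitter amount in \[0, 1\]: 0 keeps the baseline, 1 spans
#'   the whole range.
#' @return A validated `cea_scenario`.
#' @export
make_test_scenario <- function(perturb_seed, scenario = NULL, amount = 1) {
  if (is.null(scenario)) scenario <- builtin_scenarios("pdl1_ge50")
  stopifnot(amount >= 0, amount <= 1)
  if (amount == 0) return(scenario)
  set.seed(perturb_seed)
  for (r in scenario$sa_ranges) {
    base <- get_param(scenario, r$path)
    lo <- base + amount * (r$min - base)
    hi <- base + amount * (r$max - base)
    scenario <- set_param(scenario, r$path, stats::runif(1, lo, hi))
  }
  validate_scenario(scenario)
}
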
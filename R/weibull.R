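#' Weibull survival parameters
#'
#' Container for the shape/scale pair of the Weibull survival function
#' \eqn{S(t) = \exp(-\lambda t^\gamma)} used to extrapolate overall and
#' progression-free survival. Time is measured in model cycles (6 weeks by
#' default), so `scale` has units of cycle^-gamma.
#'
#' @param shape Shape \eqn{\gamma > 0} (dimensionless). Values below 1 give a
#'   decreasing hazard, above 1 an increasing hazard.
#' @param scale Scale \eqn{\lambda > 0} (per cycle^gamma).
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(shape = 0.868245, scale = 0.093252)
#' @export
weibull_params <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale),
            length(shape) == 1L, length(scale) == 1L)
  if (!is.finite(shape) || shape <= 0)
    stop("weibull shape must be a positive finite number", call. = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("weibull scale must be a positive finite number", call. = FALSE)
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull survival: S(t) = exp(-%g * t^%g)  (t in model cycles)\n",
              x$scale, x$shape))
  invisible(x)
}

as_weibull_params <- function(x) {
  if (inherits(x, "weibull_params")) return(x)
  weibull_params(x$shape, x$scale)
}

#' Weibull survival function
#'
#' Evaluates \eqn{S(t) = \exp(-\lambda t^\gamma)}.
#'
#' @param params A [weibull_params()] object.
#' @param t Time in model cycles; non-negative, vectorised.
#' @return Survival fraction(s) in (0, 1].
#' @export
weibull_survival <- function(params, t) {
  params <- as_weibull_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative and finite", call. = FALSE)
  exp(-params$scale * t^params$shape)
}

#' Per-cycle event probability from a Weibull curve
#'
#' Probability that an event (death for an OS curve, leaving the
#' progression-free state for a PFS curve) occurs during cycle `t`,
#' conditional on being event-free at the start of the cycle:
#' \deqn{p(t) = 1 - S(t+1)/S(t) = 1 - \exp(\lambda t^\gamma - \lambda (t+1)^\gamma).}
#'
#' @param params A [weibull_params()] object.
#' @param t Cycle index (non-negative, vectorised).
#' @return Probability in \[0, 1).
#' @export
cycle_event_prob <- function(params, t) {
  params <- as_weibull_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative and finite", call. = FALSE)
  1 - exp(params$scale * t^params$shape - params$scale * (t + 1)^params$shape)
}

#' Restricted mean survival time
#'
#' Integral of the Weibull survival function over \[0, horizon\], in cycles.
#' Uses the closed form via the lower incomplete gamma function,
#' \eqn{\int_0^H e^{-\lambda t^\gamma} dt =
#'  \lambda^{-1/\gamma}\,\Gamma(1/\gamma)\,P(1/\gamma, \lambda H^\gamma)/\gamma},
#' where P is the regularised gamma CDF.
#'
#' @param params A [weibull_params()] object.
#' @param horizon Upper limit of integration in cycles (> 0).
#' @return Restricted mean survival in cycles.
#' @export
weibull_rmst <- function(params, horizon) {
  params <- as_weibull_params(params)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be positive", call. = FALSE)
  g <- params$shape; l <- params$scale
  a <- 1 / g
  l^(-a) * gamma(a) * stats::pgamma(l * horizon^g, shape = a) / g
}

#' Unrestricted Weibull mean
#'
#' \eqn{\lambda^{-1/\gamma} \Gamma(1 + 1/\gamma)}, in cycles.
#'
#' @inheritParams weibull_rmst
#' @export
weibull_mean <- function(params) {
  params <- as_weibull_params(params)
  params$scale^(-1 / params$shape) * gamma(1 + 1 / params$shape)
}

#' Digitized Kaplan-Meier point series
#'
#' A validated container for (time, survival fraction) coordinates read off a
#' published Kaplan-Meier curve, the input to [fit_weibull()]. Times are in
#' model cycles.
#'
#' @param time Strictly increasing non-negative times (cycles).
#' @param surv Survival fractions in (0, 1], non-increasing; `surv` must be 1
#'   where `time == 0`.
#' @param n_at_risk Optional non-negative at-risk counts aligned with `time`.
#' @return An object of class `km_series` (a data frame with columns `time`,
#'   `surv` and optionally `n_at_risk`).
#' @export
km_series <- function(time, surv, n_at_risk = NULL) {
  if (length(time) != length(surv))
    stop("time and surv must have equal length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing (ties not allowed)", call. = FALSE)
  if (any(!is.finite(surv)) || any(surv <= 0) || any(surv > 1))
    stop("survival fractions must lie in (0, 1]", call. = FALSE)
  if (any(diff(surv) > 1e-12))
    stop("survival fractions must be non-increasing", call. = FALSE)
  if (any(time == 0) && abs(surv[time == 0] - 1) > 1e-12)
    stop("survival at time 0 must be 1", call. = FALSE)
  out <- data.frame(time = time, surv = surv)
  if (!is.null(n_at_risk)) {
    if (length(n_at_risk) != length(time))
      stop("n_at_risk must align with time", call. = FALSE)
    if (any(n_at_risk < 0)) stop("n_at_risk must be non-negative", call. = FALSE)
    out$n_at_risk <- n_at_risk
  }
  class(out) <- c("km_series", "data.frame")
  out
}

#' Read a digitized Kaplan-Meier series from delimited text
#'
#' Expects 2-3 columns: time (cycles), survival fraction, and optionally
#' number at risk. A header line is detected automatically.
#'
#' @param path Path to a delimited text file (whitespace, comma or tab).
#' @return A [km_series()] object.
#' @export
read_km <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  d <- utils::read.table(path, header = header, sep = sep,
                         strip.white = TRUE, comment.char = "#")
  if (ncol(d) < 2L) stop("expected at least two columns (time, survival)",
                         call. = FALSE)
  km_series(d[[1]], d[[2]], if (ncol(d) >= 3L) d[[3]] else NULL)
}

#' Fit a Weibull survival curve to digitized Kaplan-Meier coordinates
#'
#' The complementary log-log transform linearises the Weibull survival
#' function: \eqn{\log(-\log S) = \log\lambda + \gamma \log t}. The default
#' `transform_ols` method runs ordinary least squares of
#' `log(-log surv)` on `log(time)`; `interval_weighted` weights the same
#' regression by approximate interval event counts reconstructed from the
#' at-risk numbers (points without usable weights fall back to weight 1).
#' Points with `surv == 1` or `time == 0` carry no information on the
#' transformed scale and are dropped.
#'
#' @param series A [km_series()] object.
#' @param method `"transform_ols"` (default) or `"interval_weighted"`.
#' @return A list of class `weibull_fit` with elements `params`
#'   ([weibull_params()]), `rss` (residual sum of squares on the transformed
#'   scale) and `n_points_used`.
#' @export
fit_weibull <- function(series, method = c("transform_ols", "interval_weighted")) {
  method <- match.arg(method)
  if (!inherits(series, "km_series"))
    series <- km_series(series$time, series$surv, series$n_at_risk)
  use <- series$surv < 1 & series$surv > 0 & series$time > 0
  if (sum(use) < 3L)
    stop("need at least 3 usable points with 0 < survival < 1 and t > 0",
         call. = FALSE)
  tt <- series$time[use]
  ss <- series$surv[use]
  x <- log(tt)
  y <- log(-log(ss))
  w <- rep(1, length(x))
  if (method == "interval_weighted" && !is.null(series$n_at_risk)) {
    n <- series$n_at_risk[use]
    sprev <- c(1, ss[-length(ss)])
    ev <- n * pmax(0, (sprev - ss) / sprev)  # approx events in each interval
    if (any(ev > 0)) w <- ifelse(ev > 0, ev, 1)
  }
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  params <- weibull_params(shape = unname(fit$coefficients[2]),
                           scale = exp(unname(fit$coefficients[1])))
  structure(list(params = params,
                 rss = sum(w * fit$residuals^2),
                 n_points_used = length(x),
                 method = method),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (%s): shape = %.6f, scale = %.6f  (%d points, rss %.4g)\n",
              x$method, x$params$shape, x$params$scale, x$n_points_used, x$rss))
  invisible(x)
}
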
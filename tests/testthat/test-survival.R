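test_that("weibull_survival evaluates exp(-lambda t^gamma) with S(0) = 1", {
  pars <- random_weibull(50, seed = 11)
  for (i in seq_len(nrow(pars))) {
    p <- weibull_params(pars$shape[i], pars$scale[i])
    expect_identical(weibull_survival(p, 0), 1)
  }
  # exponential special case
  p <- weibull_params(1, 0.1)
  expect_equal(weibull_survival(p, 5), exp(-0.5), tolerance = 1e-12)
  # chemotherapy OS curve (PD-L1 >= 50%): median close to cycle 10
  p <- weibull_params(0.868245, 0.093252)
  expect_equal(weibull_survival(p, 10), 0.5022, tolerance = 1e-3)
  expect_lt(abs(weibull_survival(p, 10) - 0.5), 0.01)
  # strictly decreasing
  tt <- seq(0.5, 60, by = 0.5)
  expect_true(all(diff(weibull_survival(p, tt)) < 0))
  expect_error(weibull_survival(p, -1), "non-negative")
  expect_error(weibull_params(-1, 0.1), "shape")
  expect_error(weibull_params(1, 0), "scale")
})

test_that("cycle_event_prob equals the conditional-survival formulation", {
  p <- weibull_params(1, 0.1)
  expect_equal(cycle_event_prob(p, c(0, 3, 17)), rep(1 - exp(-0.1), 3),
               tolerance = 1e-12)  # memoryless case: constant hazard
  p <- weibull_params(0.658678, 0.112585)
  expect_equal(cycle_event_prob(p, 0), 1 - exp(-0.112585), tolerance = 1e-12)
  # oracle: M(t) = (S(t) - S(t+1)) / S(t), over 1000 random parameter triples
  pars <- random_weibull(1000, seed = 7)
  set.seed(8)
  tt <- sample(0:40, 1000, replace = TRUE)
  worst <- 0
  for (i in seq_len(1000)) {
    p <- weibull_params(pars$shape[i], pars$scale[i])
    s0 <- weibull_survival(p, tt[i])
    s1 <- weibull_survival(p, tt[i] + 1)
    m <- (s0 - s1) / s0
    got <- cycle_event_prob(p, tt[i])
    worst <- max(worst, abs(got - m))
    if (got < 0 || got > 1) fail(sprintf("probability %g out of range", got))
  }
  expect_lt(worst, 1e-12)
})

test_that("restricted mean survival matches closed forms and quadrature", {
  p <- weibull_params(1, 0.1)
  expect_equal(weibull_rmst(p, 1e4), 10, tolerance = 1e-8)      # mean 1/lambda
  expect_equal(weibull_rmst(p, 10), (1 - exp(-1)) / 0.1, tolerance = 1e-8)
  pars <- random_weibull(25, seed = 3)
  for (i in seq_len(nrow(pars))) {
    p <- weibull_params(pars$shape[i], pars$scale[i])
    expect_gte(weibull_rmst(p, 40), weibull_rmst(p, 20))  # monotone in horizon
    # independent quadrature oracle
    q <- stats::integrate(function(t) weibull_survival(p, t), 0, 35,
                          rel.tol = 1e-10)$value
    expect_equal(weibull_rmst(p, 35), q, tolerance = 1e-8)
  }
  expect_equal(weibull_mean(weibull_params(1, 0.25)), 4, tolerance = 1e-12)
})

test_that("hazard direction follows the shape parameter", {
  haz <- function(p, t) cycle_event_prob(p, t)
  inc <- haz(weibull_params(1.6, 0.05), 0:30)
  dec <- haz(weibull_params(0.6, 0.2), 1:30)
  expect_true(all(diff(inc) > 0))
  expect_true(all(diff(dec) < 0))
})

test_that("km_series validates digitized coordinates", {
  expect_s3_class(km_series(c(0, 1, 2), c(1, 0.8, 0.6)), "km_series")
  expect_error(km_series(c(1, 1, 2), c(0.9, 0.8, 0.6)), "increasing")
  expect_error(km_series(c(0, 1, 2), c(1, 0.6, 0.8)), "non-increasing")
  expect_error(km_series(c(0, 1), c(0.9, 0.8)), "time 0 must be 1")
  expect_error(km_series(c(1, 2), c(1.2, 0.8)), "\\(0, 1]")
})

test_that("fit_weibull inverts a noiseless transform exactly", {
  truth <- weibull_params(0.8, 0.09)
  tt <- 1:40
  series <- km_series(tt, weibull_survival(truth, tt))
  fit <- fit_weibull(series)
  expect_equal(fit$params$shape, 0.8, tolerance = 1e-6)
  expect_equal(fit$params$scale, 0.09, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-20)
  expect_equal(fit$n_points_used, 40L)
})

test_that("fit_weibull rejects unusable input", {
  expect_error(fit_weibull(km_series(c(1, 2), c(0.9, 0.8))), "at least 3")
  # s = 1 and t = 0 points are dropped, possibly below the minimum
  expect_error(fit_weibull(km_series(c(0, 1, 2), c(1, 0.9, 0.8))),
               "at least 3")
})

test_that("fit_weibull recovers generating parameters from simulated trials", {
  truth <- weibull_params(0.97, 0.072)
  rel_err <- function(n, seed) {
    cfg <- sim_config(truth, n_patients = n, admin_censor_cycle = 30,
                      grid = 0:30, seed = seed, digitization_noise_sd = 0)
    fit <- fit_weibull(simulate_km(cfg))
    max(abs(fit$params$shape - truth$shape) / truth$shape,
        abs(fit$params$scale - truth$scale) / truth$scale)
  }
  expect_lt(rel_err(500, seed = 3), 0.10)
  # the typical 500-patient error sits below 10%
  expect_lt(median(vapply(1:10, rel_err, 0, n = 500)), 0.10)
  # error shrinks with trial size (median over seeds, n in {100, 500, 2000})
  med <- vapply(c(100, 500, 2000), function(n)
    median(vapply(1:10, rel_err, 0, n = n)), 0)
  expect_true(all(diff(med) < 0))
})

test_that("interval weighting uses at-risk counts without breaking the fit", {
  truth <- weibull_params(0.9, 0.1)
  cfg <- sim_config(truth, n_patients = 800, admin_censor_cycle = 25,
                    grid = 0:25, seed = 5, digitization_noise_sd = 0.004)
  series <- simulate_km(cfg)
  f1 <- fit_weibull(series, "transform_ols")
  f2 <- fit_weibull(series, "interval_weighted")
  expect_false(identical(f1$params, f2$params))
  for (f in list(f1, f2)) {
    expect_lt(abs(f$params$shape - truth$shape) / truth$shape, 0.15)
    expect_lt(abs(f$params$scale - truth$scale) / truth$scale, 0.15)
  }
})

test_that("read_km parses delimited series with or without a header", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("time\tsurv\tn_at_risk", "1\t0.9\t90", "2\t0.7\t70",
               "3\t0.55\t52"), path)
  s <- read_km(path)
  expect_equal(s$surv, c(0.9, 0.7, 0.55))
  expect_equal(s$n_at_risk, c(90, 70, 52))
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("1,0.9", "2,0.7", "3,0.55"), path2)
  expect_equal(read_km(path2)$surv, c(0.9, 0.7, 0.55))
  expect_error(read_km(tempfile()), "not found")
})
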
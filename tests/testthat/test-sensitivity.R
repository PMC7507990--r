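test_that("dist_from_range matches method-of-moments hand solutions", {
  # gamma: mean 100, range width 98 -> sd 25 -> shape 16, rate 0.16
  g <- dist_from_range(100, 51, 149, "gamma")
  expect_equal(g$sd, 25)
  expect_equal(g$shape, 16)
  expect_equal(g$rate, 0.16)
  # beta: mean 0.5, sd 0.1 -> alpha = beta = 12
  b <- dist_from_range(0.5, 0.5 - 0.196, 0.5 + 0.196, "beta")
  expect_equal(b$sd, 0.1)
  expect_equal(b$shape1, 12, tolerance = 1e-12)
  expect_equal(b$shape2, 12, tolerance = 1e-12)
  # degenerate range collapses to a point mass
  d <- dist_from_range(5, 5, 5, "gamma")
  expect_identical(d$family, "degenerate")
  expect_identical(sample_dist(d, 3), rep(5, 3))
  expect_error(dist_from_range(1.2, 1, 1.4, "beta"), "inside \\(0, 1\\)")
  expect_error(dist_from_range(2, 3, 4, "gamma"), "min <= mean <= max")
  # alternative divisor convention widens the sd
  g4 <- dist_from_range(100, 51, 149, "gamma", range_divisor = 4)
  expect_equal(g4$sd, 24.5)
})

test_that("sampled moments converge to the specified mean", {
  set.seed(99)
  g <- dist_from_range(17517.15, 14013.72, 21020.58, "gamma")
  expect_lt(abs(mean(sample_dist(g, 1e5)) - 17517.15) / 17517.15, 0.01)
  b <- dist_from_range(0.473, 0.166, 0.568, "beta")
  draws <- sample_dist(b, 1e5)
  expect_lt(abs(mean(draws) - 0.473) / 0.473, 0.01)
  expect_true(all(draws > 0 & draws < 1))
})

test_that("one-way analysis spans respond to parameter influence", {
  ge50 <- builtin_scenarios("pdl1_ge50")
  # a parameter with no effect has zero span
  zero <- one_way(ge50, "ae_costs.fatigue", bounds = c(0, 0))
  expect_equal(zero$span, 0)
  # intervention drug cost dominates any single AE management cost
  nivo <- one_way(ge50, "prices.nivolumab")
  for (p in c("ae_costs.anemia", "ae_costs.neutropenia", "ae_costs.rash"))
    expect_gt(nivo$span, one_way(ge50, p)$span)
  expect_error(one_way(ge50, "prices.unobtainium"), "no sa_ranges entry")
  expect_error(one_way(ge50, "prices.unobtainium", bounds = c(1, 2)),
               "cannot resolve")
})

test_that("the ICER falls monotonically as the intervention drug gets cheaper", {
  ge50 <- builtin_scenarios("pdl1_ge50")
  base <- ge50$prices$nivolumab
  icers <- vapply(c(0, 0.15, 0.3, 0.45), function(r) {
    run_cea(set_param(ge50, "prices.nivolumab",
                      base * (1 - r)))$comparison$icer_per_qaly
  }, 0)
  expect_true(all(diff(icers) < 0))
})

test_that("tornado ranks parameters by span, deterministically", {
  ge50 <- builtin_scenarios("pdl1_ge50")
  tor <- tornado(ge50)
  expect_equal(nrow(tor), length(ge50$sa_ranges))
  expect_true(all(diff(tor$span) <= 1e-9))
  expect_true(is.finite(attr(tor, "baseline_icer")))
  # drug acquisition costs carry the largest spans
  top <- tor$parameter_path[1:2]
  expect_setequal(top, c("prices.nivolumab", "prices.ipilimumab"))
  expect_identical(tornado(ge50), tor)  # rerun is bit-identical
  # a single-entry range list yields a single-row tornado
  small <- ge50
  small$sa_ranges <- ge50$sa_ranges[1]
  expect_equal(nrow(tornado(small)), 1L)
  small$sa_ranges <- list()
  expect_error(tornado(small), "no sa_ranges")
})

test_that("PSA is seed-reproducible and collapses to the base case", {
  ge50 <- builtin_scenarios("pdl1_ge50")
  # degenerate distributions (min = max = baseline) reproduce the base case
  degen <- ge50
  degen$sa_ranges <- lapply(degen$sa_ranges, function(r) {
    v <- get_param(degen, r$path)
    list(path = r$path, min = v, max = v, dist = r$dist)
  })
  ps <- run_psa(degen, n_draws = 1, seed = 5)
  base <- run_cea(ge50)$comparison
  expect_identical(ps$delta_cost, base$delta_cost)
  expect_identical(ps$delta_qaly, base$delta_qaly)
  expect_identical(ps$icer_per_qaly, base$icer_per_qaly)
  # same seed, same samples; different seed, different samples
  a <- run_psa(ge50, n_draws = 25, seed = 7)
  b <- run_psa(ge50, n_draws = 25, seed = 7)
  c <- run_psa(ge50, n_draws = 25, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "draws"), attr(b, "draws"))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  # drawn values respect their family supports
  draws <- attr(a, "draws")
  beta_cols <- grepl("utilities|\\.ae\\.", colnames(draws))
  expect_true(all(draws[, beta_cols] > 0 & draws[, beta_cols] < 1))
  expect_true(all(draws[, !beta_cols] >= 0))
})

test_that("the acceptability curve equals brute-force counting", {
  ge50 <- builtin_scenarios("pdl1_ge50")
  ps <- run_psa(ge50, n_draws = 60, seed = 3)
  grid <- seq(0, 250000, by = 50000)
  curve <- ceac(ps, grid)
  for (i in seq_along(grid)) {
    count <- sum(grid[i] * ps$delta_qaly - ps$delta_cost > 0)
    expect_equal(curve$prob_ce[i], count / nrow(ps))
  }
  # wtp = 0: probability equals the fraction of cost-saving draws
  expect_equal(ceac(ps, 0)$prob_ce, mean(ps$delta_cost < 0))
  # all-dominant synthetic samples give probability one everywhere
  fake <- data.frame(delta_cost = -c(1, 2, 3), delta_qaly = c(1, 2, 3))
  expect_true(all(ceac(fake, grid)$prob_ce == 1))
  # monotone non-decreasing whenever every draw gains QALYs
  pos <- ps[ps$delta_qaly > 0, ]
  expect_true(all(diff(ceac(pos, seq(0, 3e5, 1e4))$prob_ce) >= 0))
})

test_that("threshold price reductions agree with a linear-model oracle", {
  lt1 <- builtin_scenarios("pdl1_lt1")
  wtp <- 150000
  # ICER(r) is linear in the price reduction r; solve for the crossing
  # analytically from two pipeline evaluations and check the bisection
  base <- run_cea(lt1)$comparison
  half <- run_cea(set_param(lt1, "prices.nivolumab",
                            lt1$prices$nivolumab * 0.5))$comparison
  stopifnot(abs(base$delta_qaly - half$delta_qaly) < 1e-9)
  slope <- (base$delta_cost - half$delta_cost) / 0.5  # net nivolumab exposure
  r_star <- (base$delta_cost - wtp * base$delta_qaly) / slope
  got <- threshold_price(lt1, "nivolumab", wtp)
  expect_lt(abs(got - r_star), 0.002)
  # an already cost-effective configuration needs no reduction
  expect_identical(threshold_price(lt1, "nivolumab", wtp = 250000), 0)
  # unreachable thresholds are flagged rather than extrapolated
  expect_message(r <- threshold_price(lt1, "nivolumab", wtp = 1000),
                 "100% price reduction")
  expect_true(is.na(r))
  expect_error(threshold_price(lt1, "unpriced_drug"), "no price entry")
})
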
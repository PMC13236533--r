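test_that("APC of a noiseless exponential matches the closed form", {
  yr <- 1990:2021
  est <- fit_loglinear_apc(yr, 100 * exp(-0.02 * (yr - 1990)))
  expect_equal(est$apc, (exp(-0.02) - 1) * 100, tolerance = 1e-10)
  expect_equal(est$beta, -0.02, tolerance = 1e-12)

  const <- fit_loglinear_apc(yr, rep(5, length(yr)))
  expect_equal(const$apc, 0, tolerance = 1e-10)
  expect_lte(const$ci_low, 0)
  expect_gte(const$ci_high, 0)
})

test_that("slope and HAC standard error match an independent Newey-West oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    yr <- 1990:2021
    rate <- 40 * exp(0.01 * (yr - 1990) + rnorm(32, 0, 0.01))
    est <- fit_loglinear_apc(yr, rate)
    oracle <- ols_nw_oracle(yr, rate)
    expect_equal(est$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(est$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("APC guards against degenerate input", {
  expect_error(fit_loglinear_apc(2000:2001, c(1, 2)), "at least 3")
  expect_error(fit_loglinear_apc(2000:2002, c(1, 0, 2)), "> 0")
})

test_that("a noiseless single exponential selects one segment and AAPC equals APC", {
  yr <- 1990:2021
  rate <- 80 * exp(-0.015 * (yr - 1990))
  fit <- fit_segmented(yr, rate)
  expect_equal(fit$n_segments, 1)
  expect_length(fit$breakpoints, 0)
  single <- fit_loglinear_apc(yr, rate)
  expect_equal(fit$segments$apc, single$apc, tolerance = 1e-10)
  expect_equal(fit$aapc$apc, single$apc, tolerance = 1e-12)
})

test_that("a noiseless two-segment trend recovers its breakpoint and slopes", {
  g <- generate_panel(one_stratum_spec(
    breakpoints = 2005, log_slopes = c(-0.01, 0.02), noise_sigma = 0))
  s <- as.data.frame(g$panel)
  fit <- fit_segmented(s$year, s$rate)
  expect_equal(fit$n_segments, 2)
  expect_equal(fit$breakpoints, 2005L)
  expect_equal(fit$segments$slope, c(-0.01, 0.02), tolerance = 1e-8)
})

test_that("BIC selects the generating segment count on noiseless data", {
  cases <- list(
    list(bp = integer(0), sl = -0.02),
    list(bp = 2004L, sl = c(-0.03, 0.01)),
    list(bp = c(2000L, 2013L), sl = c(0.01, -0.03, -0.005))
  )
  for (cs in cases) {
    g <- generate_panel(one_stratum_spec(breakpoints = cs$bp,
                                         log_slopes = cs$sl,
                                         noise_sigma = 0))
    s <- as.data.frame(g$panel)
    fit <- fit_segmented(s$year, s$rate)
    expect_equal(fit$n_segments, length(cs$sl))
    expect_equal(fit$breakpoints, cs$bp)
  }
})

test_that("exhaustive search matches a naive brute-force oracle and RSS is monotone in k", {
  for (seed in 1:8) {
    set.seed(100 + seed)
    yr <- 1990:2021
    rate <- 30 * exp(-0.01 * (yr - 1990) + rnorm(32, 0, 0.05))
    fit <- fit_segmented(yr, rate, max_segments = 3)
    for (k in 1:3) {
      expect_equal(fit$rss_by_k[k], brute_force_rss(yr, rate, k)$rss,
                   tolerance = 1e-9)
    }
    expect_true(all(diff(fit$rss_by_k) <= 1e-12))
  }
})

test_that("APC transforms back to the slope exactly", {
  set.seed(20)
  yr <- 1990:2021
  rate <- 10 * exp(0.005 * (yr - 1990) + rnorm(32, 0, 0.03))
  est <- fit_loglinear_apc(yr, rate)
  expect_equal(log(1 + est$apc / 100), est$beta, tolerance = 1e-14)
  expect_lte(est$ci_low, est$apc)
  expect_gte(est$ci_high, est$apc)
})

test_that("short series fall back to a single segment with a notice", {
  yr <- 2013:2021
  rate <- 10 * exp(-0.02 * (yr - 2013))
  expect_message(fit <- fit_segmented(yr, rate), "single segment")
  expect_equal(fit$n_segments, 1)
})

test_that("age-specific APC table covers every stratum and flags signs by construction", {
  strata <- default_strata()
  strata$breakpoints <- rep(list(integer(0)), nrow(strata))
  strata$log_slopes <- ifelse(strata$age_band == "95+",
                              list(0.005), list(-0.01))
  spec <- synthetic_spec(strata = strata, noise_sigma = 0, seed = 1)
  tab <- age_specific_apc(generate_panel(spec)$panel)
  expect_equal(nrow(tab), 12)   # 2 sexes x 6 bands, one location
  expect_true(all(tab$apc[tab$age_band == "95+"] > 0))
  expect_true(all(tab$apc[tab$age_band != "95+"] < 0))
})

test_that("incomplete strata are skipped and reported", {
  g <- generate_panel(synthetic_spec(strata = default_strata()[1:2, ],
                                     seed = 6))
  p <- as.data.frame(g$panel)
  short <- p[!(p$age_band == p$age_band[1] & p$sex == p$sex[1] &
                 p$year < 1995), ]
  panel <- burden_panel(short)
  expect_warning(tab <- age_specific_apc(panel), "incomplete")
  expect_equal(nrow(tab), 1)
  expect_length(attr(tab, "incomplete"), 1)
})
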
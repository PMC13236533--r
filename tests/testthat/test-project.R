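test_that("log-linear fits recover exact exponential slopes", {
  g <- generate_panel(one_stratum_spec(slope = log(0.98), pop_growth = 0,
                                       noise_sigma = 0))
  fits <- fit_rate_and_pop(g$panel, sex = "Both", age_band = "70-74")
  expect_equal(fits$rate$beta, log(0.98), tolerance = 1e-12)
  expect_equal(fits$pop$beta, 0, tolerance = 1e-12)
})

test_that("noisy slopes match an independent closed-form OLS oracle", {
  for (seed in 1:5) {
    g <- generate_panel(one_stratum_spec(slope = -0.015, noise_sigma = 0.02,
                                         seed = seed))
    s <- as.data.frame(g$panel)
    s <- s[s$year >= 2000, ]
    fits <- fit_rate_and_pop(g$panel, sex = "Both", age_band = "70-74")
    oracle <- ols_nw_oracle(s$year, s$rate)
    expect_equal(fits$rate$beta, oracle$beta, tolerance = 1e-10)
  }
})

test_that("projection continues the exact exponential with collapsing intervals", {
  g <- generate_panel(one_stratum_spec(slope = log(0.99), baseline = 40,
                                       pop_growth = 0.03, pop0 = 2e6,
                                       noise_sigma = 0))
  fits <- fit_rate_and_pop(g$panel, sex = "Both", age_band = "70-74")
  proj <- project_stratum(fits, horizon = 2022:2044)
  t22 <- 2022:2044 - 1990
  expect_equal(proj$rate, 40 * 0.99^t22, tolerance = 1e-9)
  expect_equal(proj$pop, 2e6 * exp(0.03 * t22), tolerance = 1e-8)
  # sigma = 0 so prediction bounds collapse onto the point path
  expect_equal(proj$rate_lower, proj$rate, tolerance = 1e-7)
  expect_equal(proj$rate_upper, proj$rate, tolerance = 1e-7)
  # rates down, numbers up: counts grow at exp(0.03)*0.99 per year
  growth <- proj$count[-1] / proj$count[-23]
  expect_equal(growth, rep(exp(0.03) * 0.99, 22), tolerance = 1e-9)
})

test_that("stratum counts and aggregates obey the count identity", {
  g <- generate_panel(synthetic_spec(seed = 17))
  proj <- project_aggregate(g$panel)
  expect_equal(proj$stratum$count,
               proj$stratum$rate * proj$stratum$pop / 1e5,
               tolerance = 1e-12)
  summed <- tapply(proj$stratum$count, proj$stratum$year, sum)
  expect_equal(proj$aggregate$count, as.numeric(summed), tolerance = 1e-12)
})

test_that("identical strata double the aggregate exactly", {
  strata <- default_strata()[default_strata()$age_band == "70-74", ]
  strata$rate_baseline <- 20; strata$pop_baseline <- 1e6
  strata$pop_log_growth <- 0.02
  strata$breakpoints <- list(integer(0), integer(0))
  strata$log_slopes <- list(-0.01, -0.01)
  spec <- synthetic_spec(strata = strata, noise_sigma = 0, seed = 1)
  panel <- generate_panel(spec)$panel
  both <- project_aggregate(panel, bands = "70-74")
  one <- project_aggregate(panel, sexes = "Male", bands = "70-74")
  expect_equal(both$aggregate$count, 2 * one$aggregate$count,
               tolerance = 1e-10)
  expect_equal(both$aggregate$rate, one$aggregate$rate, tolerance = 1e-10)
})

test_that("a 12-stratum noiseless panel aggregates to the analytic exponential sum", {
  strata <- default_strata()
  strata$breakpoints <- rep(list(integer(0)), 12)
  strata$log_slopes <- rep(list(-0.012), 12)
  spec <- synthetic_spec(strata = strata, noise_sigma = 0, seed = 1)
  panel <- generate_panel(spec)$panel
  proj <- project_aggregate(panel)
  t44 <- 2044 - 1990
  analytic <- sum(strata$rate_baseline * exp(-0.012 * t44) *
                    strata$pop_baseline * exp(strata$pop_log_growth * t44) /
                    1e5)
  got <- proj$aggregate$count[proj$aggregate$year == 2044]
  expect_equal(got, analytic, tolerance = 1e-6)
})

test_that("the anchor state is model-fitted, not the observed value", {
  g <- generate_panel(synthetic_spec(seed = 19, noise_sigma = 0.05))
  proj <- project_aggregate(g$panel)
  expect_equal(proj$anchor_state$year, 2021L)
  fits <- fit_rate_and_pop(g$panel, sex = "Male", age_band = "70-74")
  expected <- exp(fits$rate$alpha + fits$rate$beta * 2021)
  cell <- "Male:70-74"
  expect_equal(proj$anchor_state$risks[[cell]] * 1e5, expected,
               tolerance = 1e-10)
  obs <- as.data.frame(g$panel)
  obs_rate <- obs$rate[obs$sex == "Male" & obs$age_band == "70-74" &
                         obs$year == 2021]
  expect_false(isTRUE(all.equal(expected, obs_rate, tolerance = 1e-6)))
})

test_that("projected horizon states feed the decomposition", {
  g <- generate_panel(synthetic_spec(seed = 21))
  proj <- project_aggregate(g$panel)
  final <- projected_state(proj, 2044)
  d <- shapley_decompose(proj$anchor_state, final,
                         baseline_mode = "model_fitted")
  expect_equal(d$contrib_growth + d$contrib_aging + d$contrib_rate,
               d$delta_total, tolerance = 1e-9 * abs(d$delta_total))
  agg44 <- proj$aggregate[proj$aggregate$year == 2044, ]
  expect_equal(implied_deaths(final), agg44$count,
               tolerance = 1e-9 * agg44$count)
})

test_that("missing training years are reported per stratum", {
  g <- generate_panel(one_stratum_spec(years = 2005:2021))
  expect_error(
    fit_rate_and_pop(g$panel, sex = "Both", age_band = "70-74",
                     window = 2000:2021),
    "2000")
})
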
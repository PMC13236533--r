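test_that("panel states reproduce shares, risks and implied deaths", {
  g <- generate_panel(synthetic_spec(seed = 13))
  p <- as.data.frame(g$panel)
  st <- state_from_panel(g$panel, 1990, "Male")
  expect_length(st$shares, 6)
  expect_equal(sum(st$shares), 1, tolerance = 1e-12)
  obs <- sum(p$count[p$year == 1990 & p$sex == "Male"])
  expect_equal(implied_deaths(st), obs, tolerance = 1e-9)

  both <- state_from_panel(g$panel, 2021, "Both")
  expect_length(both$shares, 12)   # sex x age cells by default
  obs_both <- sum(p$count[p$year == 2021])
  expect_equal(implied_deaths(both), obs_both, tolerance = 1e-9)
})

test_that("missing age bands are named in the completeness error", {
  g <- generate_panel(synthetic_spec(seed = 13))
  p <- as.data.frame(g$panel)
  drop <- !(p$sex == "Male" & p$age_band == "85-89")
  # keep panel gap-free by dropping the whole stratum
  panel <- burden_panel(p[drop, ])
  expect_error(state_from_panel(panel, 1990, "Male"), "85-89")
})

test_that("counterfactual deaths are the mixed-state value function", {
  set.seed(30)
  base <- random_state(1990)
  final <- random_state(2021)
  expect_equal(counterfactual_deaths(base, base, base),
               implied_deaths(base))
  expect_equal(counterfactual_deaths(final, final, final),
               implied_deaths(final))
  doubled <- demographic_state(base$year, 2 * base$N, base$shares,
                               base$risks)
  expect_equal(counterfactual_deaths(doubled, base, base),
               2 * implied_deaths(base))
})

test_that("factors identical in both states contribute exactly zero", {
  set.seed(31)
  base <- random_state(1990)
  onlyN <- demographic_state(2021, base$N * 1.8, base$shares, base$risks)
  d <- shapley_decompose(base, onlyN)
  expect_identical(d$contrib_aging, 0)
  expect_identical(d$contrib_rate, 0)
  expect_equal(d$contrib_growth, d$delta_total)

  onlym <- demographic_state(2021, base$N, base$shares, base$risks * 0.6)
  d2 <- shapley_decompose(base, onlym)
  expect_identical(d2$contrib_growth, 0)
  expect_identical(d2$contrib_aging, 0)
  expect_equal(d2$contrib_rate, d2$delta_total)
})

test_that("contributions are additive and match the closed-form Shapley value", {
  set.seed(32)
  for (i in 1:200) {
    base <- random_state(1990)
    final <- random_state(2021)
    d <- shapley_decompose(base, final)
    total <- d$contrib_growth + d$contrib_aging + d$contrib_rate
    expect_equal(total, d$delta_total,
                 tolerance = 1e-9 * max(1, abs(d$delta_total)))
    phi <- shapley_closed_form(base, final)
    expect_equal(d$contrib_growth, unname(phi["N"]), tolerance = 1e-12)
    expect_equal(d$contrib_aging, unname(phi["c"]), tolerance = 1e-12)
    expect_equal(d$contrib_rate, unname(phi["m"]), tolerance = 1e-12)
  }
})

test_that("per-sex decompositions are reported separately, not summed", {
  g <- generate_panel(synthetic_spec(seed = 14))
  dm <- shapley_decompose(state_from_panel(g$panel, 1990, "Male"),
                          state_from_panel(g$panel, 2021, "Male"))
  df <- shapley_decompose(state_from_panel(g$panel, 1990, "Female"),
                          state_from_panel(g$panel, 2021, "Female"))
  db <- shapley_decompose(state_from_panel(g$panel, 1990, "Both"),
                          state_from_panel(g$panel, 2021, "Both"))
  # totals agree (same deaths), but factor attributions need not sum
  expect_equal(dm$delta_total + df$delta_total, db$delta_total,
               tolerance = 1e-9 * abs(db$delta_total))
  expect_identical(dm$sex, "Male")
  expect_identical(db$sex, "Both")
})

test_that("offset fraction quantifies how much rate decline counteracts demography", {
  d <- structure(list(delta_total = 100, contrib_growth = 600,
                      contrib_aging = 0, contrib_rate = -500,
                      baseline_mode = "descriptive", sex = "Both",
                      years = c(1990L, 2021L)),
                 class = "decomposition_result")
  expect_equal(offset_fraction(d), 500 / 600 * 100)
  d$contrib_rate <- 0
  expect_equal(offset_fraction(d), 0)
  d$contrib_rate <- -600
  expect_equal(offset_fraction(d), 100)
  d$contrib_growth <- -1; d$contrib_aging <- 0
  expect_error(offset_fraction(d), "demographic")
})

test_that("state validation enforces share and support invariants", {
  shares <- c(0.5, 0.6); names(shares) <- c("a", "b")
  risks <- c(0.1, 0.1); names(risks) <- c("a", "b")
  expect_error(demographic_state(2000, 1e5, shares, risks), "sum to 1")
  names(risks) <- c("a", "c")
  expect_error(demographic_state(2000, 1e5, c(a = 0.5, b = 0.5), risks),
               "cell names")
})
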
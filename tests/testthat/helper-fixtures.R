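# Shared fixture builders. Everything is generated in code; no files.

# A minimal valid panel data frame for hand-built scenarios.
panel_df <- function(measure = "Deaths", location = "Global",
                     sdi_group = "none", sex = "Both", age_band = "70-74",
                     year, rate, count = rate, rate_lower = NA_real_,
                     rate_upper = NA_real_, count_lower = NA_real_,
                     count_upper = NA_real_) {
  data.frame(measure = measure, location = location, sdi_group = sdi_group,
             sex = sex, age_band = age_band, year = year, rate = rate,
             count = count, rate_lower = rate_lower, rate_upper = rate_upper,
             count_lower = count_lower, count_upper = count_upper,
             stringsAsFactors = FALSE)
}

# Single-stratum synthetic spec with one exponential trend.
one_stratum_spec <- function(slope = -0.02, baseline = 50, pop0 = 1e6,
                             pop_growth = 0.03, years = 1990:2021,
                             noise_sigma = 0, seed = 1, sex = "Both",
                             age_band = "70-74", breakpoints = integer(0),
                             log_slopes = NULL) {
  if (is.null(log_slopes)) log_slopes <- slope
  strata <- data.frame(sex = sex, age_band = age_band,
                       rate_baseline = baseline, pop_baseline = pop0,
                       pop_log_growth = pop_growth,
                       stringsAsFactors = FALSE)
  strata$breakpoints <- list(as.integer(breakpoints))
  strata$log_slopes <- list(log_slopes)
  synthetic_spec(strata = strata, years = years, noise_sigma = noise_sigma,
                 ui_halfwidth = 0.3, seed = seed)
}

# Random valid demographic state over the six age bands.
random_state <- function(year = 2000, sex = "Both") {
  shares <- stats::runif(6, 0.05, 1)
  shares <- shares / sum(shares)
  names(shares) <- age_bands()
  risks <- stats::runif(6, 1e-5, 2e-3)
  names(risks) <- age_bands()
  demographic_state(year, stats::runif(1, 1e5, 1e7), shares, risks,
                    sex = sex)
}

# Independent closed-form OLS + Newey-West (Bartlett, maxlag 1) oracle for
# the slope of log(rate) on year. Deliberately avoids lm() and sandwich.
ols_nw_oracle <- function(year, rate) {
  x <- as.numeric(year); y <- log(rate)
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  Sxx <- sum((x - xbar)^2)
  beta <- sum((x - xbar) * (y - ybar)) / Sxx
  alpha <- ybar - beta * xbar
  u <- y - alpha - beta * x
  # scores for the slope in the (1, x) regression; bread = (X'X)^-1
  X <- cbind(1, x)
  XtX_inv <- solve(t(X) %*% X)
  scores <- X * u
  gamma0 <- t(scores) %*% scores
  gamma1 <- t(scores[-1, , drop = FALSE]) %*% scores[-n, , drop = FALSE]
  w1 <- 1 - 1 / 2  # Bartlett weight at lag 1 with maxlag 1
  meat <- (gamma0 + w1 * (gamma1 + t(gamma1))) * n / (n - 2)
  V <- XtX_inv %*% meat %*% XtX_inv
  list(beta = beta, se = sqrt(V[2, 2]))
}

# Closed-form three-factor Shapley value, used only as an oracle against
# the package's permutation enumeration.
shapley_closed_form <- function(base, final) {
  v <- function(switched) {
    pick <- function(f) if (f %in% switched) final else base
    counterfactual_deaths(pick("N"), pick("c"), pick("m"))
  }
  phi <- function(f) {
    others <- setdiff(c("N", "c", "m"), f)
    subsets <- list(character(0), others[1], others[2], others)
    w <- c(2, 1, 1, 2) / 6  # |S|! (3-|S|-1)! / 3!
    sum(vapply(seq_along(subsets), function(i) {
      S <- subsets[[i]]
      w[i] * (v(c(S, f)) - v(S))
    }, numeric(1)))
  }
  c(N = phi("N"), c = phi("c"), m = phi("m"))
}

# Naive brute-force best RSS for continuous piecewise log-linear fits with
# k segments, by explicit nested loops over admissible integer breakpoints.
# Independent of the package's search (uses lm()).
brute_force_rss <- function(year, rate, k, min_len = 5) {
  x <- as.numeric(year); y <- log(rate)
  y0 <- min(x); y1 <- max(x)
  fit_rss <- function(bps) {
    d <- data.frame(y = y, x = x)
    form <- "y ~ x"
    for (j in seq_along(bps)) {
      d[[paste0("h", j)]] <- pmax(x - bps[j], 0)
      form <- paste0(form, " + h", j)
    }
    sum(resid(lm(as.formula(form), data = d))^2)
  }
  best <- Inf; best_bps <- NULL
  if (k == 1) {
    best <- fit_rss(integer(0))
  } else if (k == 2) {
    for (b1 in (y0 + min_len):(y1 - min_len)) {
      r <- fit_rss(b1)
      if (r < best) { best <- r; best_bps <- b1 }
    }
  } else if (k == 3) {
    for (b1 in (y0 + min_len):(y1 - 2 * min_len)) {
      for (b2 in (b1 + min_len):(y1 - min_len)) {
        r <- fit_rss(c(b1, b2))
        if (r < best) { best <- r; best_bps <- c(b1, b2) }
      }
    }
  } else {
    stop("oracle supports k <= 3")
  }
  list(rss = best, breakpoints = best_bps)
}
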
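# Empirical age-specific log-linear extrapolation: independent OLS fits to
# ln(rate) and ln(population) per stratum over a training window, point
# projection of both paths, t-based prediction intervals for rates on the
# log scale, and aggregation of projected counts across strata. Populations
# are projected as point paths, so count uncertainty reflects rate
# uncertainty only.

# OLS of ln(value) on year with the moments needed for out-of-sample
# prediction intervals.
loglinear_fit <- function(year, value) {
  if (length(year) < 5) {
    stop("loglinear_fit: training window must span at least 5 years",
         call. = FALSE)
  }
  if (any(is.na(value)) || any(value <= 0)) {
    stop("loglinear_fit: all values must be > 0", call. = FALSE)
  }
  ord <- order(year)
  x <- as.numeric(year[ord]); y <- log(value[ord])
  n <- length(x)
  xbar <- mean(x); Sxx <- sum((x - xbar)^2)
  beta <- sum((x - xbar) * (y - mean(y))) / Sxx
  alpha <- mean(y) - beta * xbar
  res <- y - (alpha + beta * x)
  s2 <- sum(res^2) / (n - 2)
  structure(list(alpha = alpha, beta = beta, sigma2 = s2, n = n,
                 xbar = xbar, Sxx = Sxx, window = range(x)),
            class = "loglinear_fit")
}

# Point path and 95% t prediction interval on the natural scale.
predict_loglinear <- function(fit, years, level = 0.95) {
  x <- as.numeric(years)
  mu <- fit$alpha + fit$beta * x
  se_pred <- sqrt(fit$sigma2 * (1 + 1 / fit$n + (x - fit$xbar)^2 / fit$Sxx))
  tq <- qt(1 - (1 - level) / 2, df = fit$n - 2)
  data.frame(year = years, fit = exp(mu),
             lower = exp(mu - tq * se_pred),
             upper = exp(mu + tq * se_pred))
}

#' Fit log-linear trends to one stratum's rate and population series
#'
#' Reconstructs the stratum's population from its rates and counts, then
#' fits two independent OLS models on the log scale over the training
#' window: one to the rate series and one to the population series. The
#' fits carry the design moments needed for t-based prediction intervals.
#'
#' @param panel A [burden_panel()].
#' @param sex,age_band Stratum selectors.
#' @param measure Measure, default `"Deaths"`.
#' @param location Optional location filter.
#' @param window Training years, default `2000:2021`.
#' @return List with elements `rate` and `pop` (each a `loglinear_fit`)
#'   and the stratum identifiers.
#' @export
fit_rate_and_pop <- function(panel, sex, age_band, measure = "Deaths",
                             location = NULL, window = 2000:2021) {
  stopifnot(is_burden_panel(panel))
  s <- stratum_series(panel, measure = measure, location = location,
                      sex = sex, age_band = age_band)
  s <- s[s$year %in% window, , drop = FALSE]
  miss <- setdiff(window, s$year)
  if (length(miss) > 0) {
    stop("fit_rate_and_pop: years missing from training window for ",
         sex, " ", age_band, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pop <- reconstruct_population(s$rate, s$count)
  list(rate = loglinear_fit(s$year, s$rate),
       pop = loglinear_fit(s$year, pop),
       sex = sex, age_band = age_band, measure = measure)
}

#' Project one stratum over a horizon
#'
#' Continues the fitted exponential rate and population paths over the
#' horizon years. Rates carry 95% t prediction intervals (computed on the
#' log scale and exponentiated); populations are point paths; counts and
#' count bounds are `rate (bounds) * population / 1e5`.
#'
#' @param fits Output of [fit_rate_and_pop()].
#' @param horizon Years to project, default `2022:2044`.
#' @return Tibble with `year`, `rate`, `rate_lower`, `rate_upper`, `pop`,
#'   `count`, `count_lower`, `count_upper`.
#' @export
project_stratum <- function(fits, horizon = 2022:2044) {
  pr <- predict_loglinear(fits$rate, horizon)
  pp <- predict_loglinear(fits$pop, horizon)
  tibble::tibble(
    year = as.integer(horizon),
    rate = pr$fit, rate_lower = pr$lower, rate_upper = pr$upper,
    pop = pp$fit,
    count = pr$fit * pp$fit / RATE_SCALE,
    count_lower = pr$lower * pp$fit / RATE_SCALE,
    count_upper = pr$upper * pp$fit / RATE_SCALE
  )
}

#' Project all age-sex strata and aggregate
#'
#' Fits [fit_rate_and_pop()] to every age-sex stratum, projects each over
#' the horizon, and sums counts and populations to the aggregate; the
#' aggregate rate is total count / total population x 100,000. Aggregated
#' count bounds are sums of stratum bounds (perfect-dependence,
#' conservative) by default; `bounds = "rss"` combines half-widths
#' root-sum-square instead (independence). Also returns the model-fitted
#' demographic state at the anchor year (last training year), the baseline
#' used by [shapley_decompose()] in `model_fitted` mode.
#'
#' @param panel A [burden_panel()] with Male/Female rows for all six bands.
#' @param measure Measure, default `"Deaths"`.
#' @param location Optional location filter.
#' @param window Training years, default `2000:2021`.
#' @param horizon Projection years, default `2022:2044`.
#' @param sexes Sex strata to project, default `c("Male", "Female")`.
#' @param bands Age bands to project, default all six five-year bands.
#' @param bounds `"sum"` or `"rss"` aggregation of count bounds.
#' @return A `projection_result`: `stratum` (per-stratum tibble),
#'   `aggregate` (tibble with summed counts, populations, aggregate rate
#'   and bounds), `anchor_state` (a [demographic_state()]), `anchor_year`,
#'   `window`, `horizon`.
#' @export
project_aggregate <- function(panel, measure = "Deaths", location = NULL,
                              window = 2000:2021, horizon = 2022:2044,
                              sexes = c("Male", "Female"),
                              bands = age_bands(),
                              bounds = c("sum", "rss")) {
  stopifnot(is_burden_panel(panel))
  bounds <- match.arg(bounds)
  anchor_year <- max(window)

  strata <- expand.grid(sex = sexes, age_band = bands,
                        stringsAsFactors = FALSE)
  per <- list(); failures <- character(0)
  anchor_pop <- numeric(0); anchor_risk <- numeric(0)
  for (r in seq_len(nrow(strata))) {
    sx <- strata$sex[r]; ab <- strata$age_band[r]
    fits <- tryCatch(
      fit_rate_and_pop(panel, sex = sx, age_band = ab, measure = measure,
                       location = location, window = window),
      error = function(e) e)
    if (inherits(fits, "error")) {
      failures <- c(failures, paste0(sx, " ", ab, ": ",
                                     conditionMessage(fits)))
      next
    }
    proj <- project_stratum(fits, horizon)
    proj$sex <- sx; proj$age_band <- ab
    per[[r]] <- proj

    cell <- if (length(sexes) > 1) paste(sx, ab, sep = ":") else ab
    fitted_rate <- predict_loglinear(fits$rate, anchor_year)$fit
    fitted_pop <- predict_loglinear(fits$pop, anchor_year)$fit
    anchor_pop[cell] <- fitted_pop
    anchor_risk[cell] <- fitted_rate / RATE_SCALE
  }
  if (length(failures) > 0) {
    stop("project_aggregate: stratum fit failure(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  stratum <- do.call(rbind, per)

  combine <- function(col) {
    as.numeric(tapply(stratum[[col]], stratum$year, sum))
  }
  yrs <- sort(unique(stratum$year))
  count <- combine("count"); pop <- combine("pop")
  if (bounds == "sum") {
    count_lower <- combine("count_lower")
    count_upper <- combine("count_upper")
  } else {
    half_lo <- stratum$count - stratum$count_lower
    half_hi <- stratum$count_upper - stratum$count
    rss <- function(h) sqrt(as.numeric(tapply(h^2, stratum$year, sum)))
    count_lower <- count - rss(half_lo)
    count_upper <- count + rss(half_hi)
  }
  aggregate <- tibble::tibble(
    year = yrs, count = count, pop = pop,
    rate = count / pop * RATE_SCALE,
    count_lower = count_lower, count_upper = count_upper,
    rate_lower = count_lower / pop * RATE_SCALE,
    rate_upper = count_upper / pop * RATE_SCALE
  )

  N <- sum(anchor_pop)
  anchor_state <- demographic_state(
    anchor_year, N, anchor_pop / N, anchor_risk,
    sex = if (length(sexes) > 1) "Both" else sexes
  )

  out <- list(stratum = tibble::as_tibble(stratum), aggregate = aggregate,
              anchor_state = anchor_state, anchor_year = anchor_year,
              window = range(window), horizon = range(horizon),
              measure = measure)
  class(out) <- "projection_result"
  out
}

#' @export
print.projection_result <- function(x, ...) {
  last <- x$aggregate[nrow(x$aggregate), ]
  cat(sprintf("Projection of %s, trained %d-%d, horizon %d-%d\n",
              x$measure, x$window[1], x$window[2],
              x$horizon[1], x$horizon[2]))
  cat(sprintf("  %d: %.0f events (rate %.2f per 100,000), 95%% PI %.0f-%.0f\n",
              last$year, last$count, last$rate,
              last$count_lower, last$count_upper))
  cat(sprintf("  model-fitted %d baseline: %.0f events\n",
              x$anchor_year, implied_deaths(x$anchor_state)))
  invisible(x)
}

#' Demographic state of the projected horizon endpoint
#'
#' Builds the [demographic_state()] implied by the projection at one
#' horizon year (default the last), for use as the `final` state of a
#' [shapley_decompose()] of projected change.
#'
#' @param projection A `projection_result`.
#' @param year Horizon year, default the last projected year.
#' @return A [demographic_state()].
#' @export
projected_state <- function(projection, year = NULL) {
  stopifnot(inherits(projection, "projection_result"))
  s <- as.data.frame(projection$stratum)
  if (is.null(year)) year <- max(s$year)
  s <- s[s$year == year, , drop = FALSE]
  multi_sex <- length(unique(s$sex)) > 1
  cell <- if (multi_sex) paste(s$sex, s$age_band, sep = ":") else s$age_band
  pop <- s$pop; names(pop) <- cell
  risks <- s$rate / RATE_SCALE; names(risks) <- cell
  demographic_state(year, sum(pop), pop / sum(pop), risks,
                    sex = if (multi_sex) "Both" else s$sex[1])
}
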
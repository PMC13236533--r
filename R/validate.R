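# Out-of-sample validation of the projection model. Hindcasting fits the
# primary log-linear model on an early window and scores its forecasts
# against held-out later observations (MAPE, MAE, RMSE, 95% prediction-
# interval coverage). Robustness compares the primary forecast path with a
# local-linear-trend structural model (UCM) and an AIC-selected ARIMA,
# both fitted on the log rate scale by default.

#' Hindcast the log-linear rate model
#'
#' Fits the primary log-linear model on the training window and evaluates
#' its forecasts against the observed test-window rates:
#' `MAPE = mean(|obs - pred| / obs) * 100`, MAE and RMSE in rate units, and
#' the share of test years whose observation falls inside the 95%
#' prediction interval.
#'
#' @param year,rate Observed series covering both windows.
#' @param train,test Disjoint year windows, defaults `2000:2014` and
#'   `2015:2021`.
#' @return A `hindcast_report`: `mape`, `mae`, `rmse`, `coverage` (all the
#'   error metrics on the natural rate scale, coverage in percent),
#'   `detail` (per-year tibble), `train`, `test`.
#' @export
hindcast <- function(year, rate, train = 2000:2014, test = 2015:2021) {
  if (length(intersect(train, test)) > 0) {
    stop("hindcast: train and test windows overlap", call. = FALSE)
  }
  miss <- setdiff(c(train, test), year)
  if (length(miss) > 0) {
    stop("hindcast: years not observed: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fit <- loglinear_fit(year[year %in% train], rate[year %in% train])
  pred <- predict_loglinear(fit, sort(test))
  obs <- rate[match(pred$year, year)]

  err <- obs - pred$fit
  inside <- obs >= pred$lower & obs <= pred$upper
  out <- list(
    mape = mean(abs(err) / obs) * 100,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    coverage = mean(inside) * 100,
    detail = tibble::tibble(year = pred$year, observed = obs,
                            predicted = pred$fit, lower = pred$lower,
                            upper = pred$upper, inside = inside),
    train = range(train), test = range(test)
  )
  class(out) <- "hindcast_report"
  out
}

#' @export
print.hindcast_report <- function(x, ...) {
  cat(sprintf("Hindcast: train %d-%d, test %d-%d\n",
              x$train[1], x$train[2], x$test[1], x$test[2]))
  cat(sprintf("  MAPE %.2f%%, MAE %.4f, RMSE %.4f, 95%% PI coverage %.0f%%\n",
              x$mape, x$mae, x$rmse, x$coverage))
  invisible(x)
}

# ARIMA candidate with a deterministic trend term: include.mean for d = 0,
# a linear drift regressor for d = 1 (so (0,1,0)+drift is a random walk
# with drift). Returns NULL when the fit fails or does not converge.
fit_arima_candidate <- function(y, order) {
  drift_x <- matrix(seq_along(y), ncol = 1)
  res <- tryCatch({
    if (order[2] == 0) {
      f <- arima(y, order = order, include.mean = TRUE, method = "ML")
    } else {
      f <- arima(y, order = order, xreg = drift_x, method = "ML")
    }
    if (!is.null(f$code) && f$code != 0) NULL else f
  }, error = function(e) NULL, warning = function(w) NULL)
  res
}

forecast_arima <- function(fit, order, n_obs, h) {
  # predict.Arima re-evaluates the fit call's xreg symbol in this frame
  drift_x <- matrix(seq_len(n_obs), ncol = 1)
  if (order[2] == 0) {
    predict(fit, n.ahead = h)$pred
  } else {
    predict(fit, n.ahead = h,
            newxreg = matrix(n_obs + seq_len(h), ncol = 1))$pred
  }
}

#' Compare the primary forecast with UCM and ARIMA alternatives
#'
#' Projects an observed rate series over a horizon with three models: the
#' primary log-linear extrapolation, an unobserved-components model with a
#' local linear trend ([stats::StructTS] `type = "trend"`), and an ARIMA
#' whose order is selected by AIC over `p, q in {0,1,2}`, `d in {0,1}`
#' (each candidate including a mean or drift term). Alternatives are
#' fitted on the log rate scale by default for positivity and
#' comparability. Divergence from the primary path is summarised as the
#' mean absolute percentage difference over the horizon and the percentage
#' difference at the final year, both with the primary forecast as the
#' denominator.
#'
#' @param year,rate Observed series (e.g. the aggregated 70+ death rate).
#' @param horizon Forecast years, default `2022:2044`.
#' @param log_scale Fit the alternatives on `ln(rate)` (default `TRUE`).
#' @return A `model_comparison`: `comparison` tibble (model, mapd,
#'   pct_diff_at_horizon, converged), `forecasts` tibble of the three
#'   paths, `arima_order`.
#' @export
compare_models <- function(year, rate, horizon = 2022:2044,
                           log_scale = TRUE) {
  if (any(rate <= 0)) {
    stop("compare_models: all rates must be > 0", call. = FALSE)
  }
  ord <- order(year)
  year <- year[ord]; rate <- rate[ord]
  if (max(year) >= min(horizon)) {
    stop("compare_models: horizon must start after the last observation",
         call. = FALSE)
  }
  h <- length(horizon)
  y <- if (log_scale) log(rate) else rate
  back <- if (log_scale) exp else identity

  primary <- predict_loglinear(loglinear_fit(year, rate), horizon)$fit

  ucm_path <- rep(NA_real_, h); ucm_ok <- FALSE
  ucm <- tryCatch(StructTS(ts(y, start = year[1]), type = "trend"),
                  error = function(e) NULL)
  if (!is.null(ucm)) {
    ucm_path <- back(as.numeric(predict(ucm, n.ahead = h)$pred))
    ucm_ok <- TRUE
  }

  grid <- expand.grid(p = 0:2, d = 0:1, q = 0:2)
  best <- NULL; best_aic <- Inf; best_order <- NULL
  for (i in seq_len(nrow(grid))) {
    o <- c(grid$p[i], grid$d[i], grid$q[i])
    f <- fit_arima_candidate(y, o)
    if (!is.null(f) && AIC(f) < best_aic) {
      best <- f; best_aic <- AIC(f); best_order <- o
    }
  }
  arima_path <- rep(NA_real_, h); arima_ok <- FALSE
  if (!is.null(best)) {
    arima_path <- back(as.numeric(
      forecast_arima(best, best_order, length(y), h)))
    arima_ok <- TRUE
  }

  divergence <- function(alt) {
    if (any(is.na(alt))) return(c(NA_real_, NA_real_))
    c(mean(abs(alt - primary) / primary) * 100,
      (alt[h] - primary[h]) / primary[h] * 100)
  }
  du <- divergence(ucm_path); da <- divergence(arima_path)

  out <- list(
    comparison = tibble::tibble(
      model = c("ucm", "arima"),
      mapd = c(du[1], da[1]),
      pct_diff_at_horizon = c(du[2], da[2]),
      converged = c(ucm_ok, arima_ok)
    ),
    forecasts = tibble::tibble(year = as.integer(horizon),
                               primary = primary, ucm = ucm_path,
                               arima = arima_path),
    arima_order = best_order,
    log_scale = log_scale
  )
  if (!ucm_ok) warning("compare_models: UCM fit failed; model skipped")
  if (!arima_ok) warning("compare_models: no ARIMA candidate converged")
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Forecast robustness vs primary log-linear model\n")
  cmp <- x$comparison
  for (i in seq_len(nrow(cmp))) {
    lab <- cmp$model[i]
    if (lab == "arima" && !is.null(x$arima_order)) {
      lab <- sprintf("arima(%d,%d,%d)", x$arima_order[1], x$arima_order[2],
                     x$arima_order[3])
    }
    cat(sprintf("  %-12s MAPD %.2f%%, final-year diff %+.2f%%%s\n",
                lab, cmp$mapd[i], cmp$pct_diff_at_horizon[i],
                if (cmp$converged[i]) "" else " (did not converge)"))
  }
  invisible(x)
}
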
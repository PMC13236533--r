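# Segmented log-linear trend analysis: OLS on ln(rate) vs calendar year,
# Newey-West (Bartlett kernel, maxlag 1) standard errors, annual percent
# change APC = (exp(beta) - 1) * 100, exhaustive integer-year breakpoint
# search with BIC model selection, and a full-period AAPC from a separate
# single-segment fit.

Z95 <- 1.96  # conventional normal quantile for the 95% APC intervals

# Newey-West standard error of the year slope. Bartlett kernel, maxlag 1,
# no prewhitening, with the n/(n-k) small-sample correction. A numerically
# perfect fit short-circuits to SE 0 (summary.lm warns on such fits).
nw_slope_se <- function(fit) {
  r <- stats::resid(fit)
  if (sum(r^2) < length(r) * 1e-20) return(0)
  V <- sandwich::NeweyWest(fit, lag = 1, prewhite = FALSE, adjust = TRUE)
  sqrt(V[2, 2])
}

apc_from_beta <- function(beta, se) {
  list(apc = (exp(beta) - 1) * 100,
       ci_low = (exp(beta - Z95 * se) - 1) * 100,
       ci_high = (exp(beta + Z95 * se) - 1) * 100)
}

#' Annual percent change from a log-linear fit
#'
#' Fits `ln(rate) ~ year` by OLS, computes the Newey-West (maxlag 1) robust
#' standard error of the slope, and transforms to the annual percent change
#' scale: `APC = (exp(beta) - 1) * 100` with a 95% interval from
#' `beta +- 1.96 * SE`.
#'
#' @param year Integer calendar years (at least 3).
#' @param rate Strictly positive rates, same length as `year`.
#' @return An `apc_estimate`: list with `apc`, `ci_low`, `ci_high` (percent),
#'   `beta`, `se`, `intercept`, `n`.
#' @export
fit_loglinear_apc <- function(year, rate) {
  if (length(year) != length(rate)) {
    stop("fit_loglinear_apc: year and rate lengths differ", call. = FALSE)
  }
  if (length(year) < 3) {
    stop("fit_loglinear_apc: need at least 3 observations", call. = FALSE)
  }
  if (any(is.na(rate)) || any(rate <= 0)) {
    stop("fit_loglinear_apc: all rates must be > 0", call. = FALSE)
  }
  ord <- order(year)
  year <- year[ord]; rate <- rate[ord]
  fit <- lm(log(rate) ~ year)
  beta <- unname(coef(fit)[2])
  se <- nw_slope_se(fit)
  out <- c(apc_from_beta(beta, se),
           list(beta = beta, se = se,
                intercept = unname(coef(fit)[1]), n = length(year)))
  class(out) <- "apc_estimate"
  out
}

#' @export
print.apc_estimate <- function(x, ...) {
  cat(sprintf("APC %.3f%% (95%% CI %.3f to %.3f), beta = %.5f (SE %.5f), n = %d\n",
              x$apc, x$ci_low, x$ci_high, x$beta, x$se, x$n))
  invisible(x)
}

# All admissible breakpoint sets for n_seg segments: integer years strictly
# inside [y0, y1], each segment's boundary-year span >= min_len. Returned
# as a matrix with one row per candidate set (0 columns for n_seg = 1).
enumerate_breakpoints <- function(y0, y1, n_seg, min_len) {
  k <- n_seg - 1
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  # substitute c_i = b_i - (i-1)*(min_len-1): strictly increasing integer
  # c (combn) maps one-to-one onto b with pairwise spacing >= min_len
  lo <- y0 + min_len
  hi <- y1 - min_len - (k - 1) * (min_len - 1)
  if (hi < lo) return(matrix(integer(0), nrow = 0, ncol = k))
  cand <- lo:hi
  if (length(cand) < k) return(matrix(integer(0), nrow = 0, ncol = k))
  if (k == 1) return(matrix(cand, ncol = 1))
  cmb <- t(utils::combn(cand, k))
  cmb + matrix(rep(0:(k - 1) * (min_len - 1), each = nrow(cmb)),
               nrow = nrow(cmb))
}

# Continuous piecewise-linear OLS of y on x with kinks at the given
# breakpoints; returns RSS, per-segment slopes and fitted values.
piecewise_ols <- function(x, y, bps) {
  X <- cbind(1, x)
  for (b in bps) X <- cbind(X, pmax(x - b, 0))
  fit <- .lm.fit(X, y)
  res <- fit$residuals
  slopes <- cumsum(fit$coefficients[-1])
  list(rss = sum(res^2), slopes = unname(slopes),
       fitted = y - res, coef = fit$coefficients)
}

# BIC for a piecewise fit: n*ln(RSS/n) + p*ln(n) with p = (#slopes) +
# (#breakpoints) + 1 intercept = 2 * n_segments. RSS is floored at
# n * 1e-20 so numerically perfect fits compare by parameter count alone.
piecewise_bic <- function(rss, n, n_seg) {
  rss <- max(rss, n * 1e-20)
  n * log(rss / n) + 2 * n_seg * log(n)
}

#' Segmented log-linear trend fit with BIC-selected breakpoints
#'
#' For each candidate segment count from 1 to `max_segments`, exhaustively
#' searches all integer-year breakpoint sets satisfying the minimum segment
#' length and fits the continuous piecewise-linear model to `ln(rate)`;
#' the candidate minimising the BIC (ties broken toward fewer segments) is
#' returned. Per-segment APC point estimates come from the constrained
#' piecewise fit; their standard errors come from Newey-West inference on
#' per-segment OLS refits. The full-period AAPC is a separate single
#' log-linear fit over all years, never a weighted average of segment APCs.
#'
#' @param year Consecutive integer calendar years.
#' @param rate Strictly positive rates.
#' @param max_segments Maximum number of segments to consider (1-6).
#' @param min_segment_len Minimum boundary-year span of a segment, in years.
#' @return A `segmented_fit`: list with `breakpoints`, `n_segments`,
#'   `segments` (tibble: start, end, slope, se, apc, ci_low, ci_high),
#'   `bic`, `bic_by_k`, `rss_by_k` (best RSS per candidate segment count),
#'   `aapc` (an `apc_estimate`), `fitted_log_rates`.
#' @export
fit_segmented <- function(year, rate, max_segments = 6, min_segment_len = 5) {
  if (any(is.na(rate)) || any(rate <= 0)) {
    stop("fit_segmented: all rates must be > 0", call. = FALSE)
  }
  ord <- order(year)
  year <- as.integer(year[ord]); rate <- rate[ord]
  if (!all(diff(year) == 1L)) {
    stop("fit_segmented: years must be consecutive", call. = FALSE)
  }
  n <- length(year)
  y0 <- year[1]; y1 <- year[n]
  span <- y1 - y0
  ly <- log(rate)

  if (span < 2 * min_segment_len && max_segments > 1) {
    message("fit_segmented: range too short for 2 segments of ",
            min_segment_len, " years; fitting a single segment")
    max_segments <- 1
  }

  best <- NULL
  bic_by_k <- numeric(0)
  rss_by_k <- numeric(0)
  for (k in seq_len(max_segments)) {
    sets <- enumerate_breakpoints(y0, y1, k, min_segment_len)
    if (nrow(sets) == 0) break
    best_k <- NULL
    for (i in seq_len(nrow(sets))) {
      f <- piecewise_ols(year, ly, sets[i, ])
      if (is.null(best_k) || f$rss < best_k$rss) {
        best_k <- f
        best_k$bps <- as.integer(sets[i, ])
      }
    }
    bic_k <- piecewise_bic(best_k$rss, n, k)
    bic_by_k[k] <- bic_k
    rss_by_k[k] <- best_k$rss
    if (is.null(best) || bic_k < best$bic) {
      best <- best_k
      best$bic <- bic_k
      best$k <- k
    }
  }

  bounds <- c(y0, best$bps, y1)
  seg_rows <- lapply(seq_len(best$k), function(j) {
    in_seg <- year >= bounds[j] & year <= bounds[j + 1]
    refit <- lm(ly[in_seg] ~ year[in_seg])
    se <- nw_slope_se(refit)
    slope <- best$slopes[j]
    ci <- apc_from_beta(slope, se)
    data.frame(start = bounds[j], end = bounds[j + 1], slope = slope,
               se = se, apc = ci$apc, ci_low = ci$ci_low,
               ci_high = ci$ci_high)
  })

  out <- list(
    breakpoints = best$bps,
    n_segments = best$k,
    segments = tibble::as_tibble(do.call(rbind, seg_rows)),
    bic = best$bic,
    bic_by_k = bic_by_k,
    rss_by_k = rss_by_k,
    aapc = fit_loglinear_apc(year, rate),
    fitted_log_rates = tibble::tibble(year = year, fitted = best$fitted),
    rss = best$rss,
    years = c(y0, y1)
  )
  class(out) <- "segmented_fit"
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented log-linear fit, %d-%d: %d segment(s)",
              x$years[1], x$years[2], x$n_segments))
  if (length(x$breakpoints) > 0) {
    cat(", breakpoints ", paste(x$breakpoints, collapse = ", "), sep = "")
  }
  cat(sprintf(" (BIC %.2f)\n", x$bic))
  s <- x$segments
  for (j in seq_len(nrow(s))) {
    cat(sprintf("  %d-%d: APC %.2f%% (%.2f to %.2f)\n",
                s$start[j], s$end[j], s$apc[j], s$ci_low[j], s$ci_high[j]))
  }
  cat(sprintf("  AAPC %.2f%% (%.2f to %.2f)\n",
              x$aapc$apc, x$aapc$ci_low, x$aapc$ci_high))
  invisible(x)
}

#' Age-specific APC table across panel strata
#'
#' Fits [fit_loglinear_apc()] to every five-year-band stratum of the panel
#' (aggregate 70+ rows are ignored). Strata whose year coverage falls short
#' of the panel-wide span are skipped and listed in the `incomplete`
#' attribute.
#'
#' @param panel A [burden_panel()].
#' @param measure Measure to analyse, default `"Deaths"`.
#' @return Tibble with the stratum key columns and `apc`, `ci_low`,
#'   `ci_high`, `beta`, `se`; attribute `incomplete` names skipped strata.
#' @export
age_specific_apc <- function(panel, measure = "Deaths") {
  stopifnot(is_burden_panel(panel))
  p <- as.data.frame(panel)
  p <- p[p$measure == measure & p$age_band %in% age_bands(), , drop = FALSE]
  if (nrow(p) == 0) {
    stop("age_specific_apc: no five-year-band rows for measure ", measure,
         call. = FALSE)
  }
  full_span <- range(p$year)
  rows <- list(); incomplete <- character(0)
  for (s in split(p, panel_key(p))) {
    s <- s[order(s$year), ]
    if (min(s$year) > full_span[1] || max(s$year) < full_span[2]) {
      incomplete <- c(incomplete, panel_key(s[1, ]))
      next
    }
    est <- fit_loglinear_apc(s$year, s$rate)
    rows[[length(rows) + 1]] <- data.frame(
      location = s$location[1], sdi_group = s$sdi_group[1], sex = s$sex[1],
      age_band = s$age_band[1], apc = est$apc, ci_low = est$ci_low,
      ci_high = est$ci_high, beta = est$beta, se = est$se,
      stringsAsFactors = FALSE
    )
  }
  if (length(incomplete) > 0) {
    warning("age_specific_apc: skipped incomplete strata: ",
            paste(incomplete, collapse = "; "))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$location, out$sex,
                   match(out$age_band, age_bands())), , drop = FALSE]
  out <- tibble::as_tibble(out)
  attr(out, "incomplete") <- incomplete
  out
}
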
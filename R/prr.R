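# Descriptive period rate ratios: mean annual rate within consecutive
# 5-year calendar bins divided by the mean rate in the reference
# (first) bin. Bounds divide the period's mean lower/upper estimates by
# the reference period's POINT mean — a descriptive summary, not an
# inferential confidence interval.

period_label <- function(start, end) {
  if (start == end) as.character(start) else paste0(start, "-", end)
}

#' Period rate ratios relative to the first calendar period
#'
#' Groups each stratum's years into consecutive bins of `period_length`
#' years starting at the series' first year, averages the annual point
#' rates within each bin, and divides by the reference (first) bin's mean.
#' A partial terminal bin is kept and labelled by its actual span (for a
#' 1990-2021 series with 5-year bins the last period is "2020-2021");
#' `min_coverage` can drop bins covering less than that fraction of a full
#' period. Bound ratios divide the bin's mean lower and upper estimates by
#' the reference bin's point mean.
#'
#' @param panel A [burden_panel()].
#' @param period_length Bin width in years (default 5).
#' @param min_coverage Minimum fraction of `period_length` a terminal bin
#'   must cover to be kept (default 0 keeps all).
#' @return Tibble with stratum keys, `period`, `years_in_period`,
#'   `mean_rate`, `prr`, `prr_low`, `prr_high`; reference bin has
#'   `prr = 1` exactly.
#' @export
period_rate_ratios <- function(panel, period_length = 5, min_coverage = 0) {
  stopifnot(is_burden_panel(panel))
  p <- as.data.frame(panel)
  if (any(is.na(p$rate)) || any(p$rate <= 0)) {
    stop("period_rate_ratios: all rates must be > 0", call. = FALSE)
  }
  rows <- list()
  for (s in split(p, panel_key(p))) {
    s <- s[order(s$year), ]
    y0 <- min(s$year)
    bin <- (s$year - y0) %/% period_length
    if (sum(bin == 0) < period_length) {
      stop("period_rate_ratios: reference period not fully covered in ",
           "stratum ", panel_key(s[1, ]), call. = FALSE)
    }
    ref_mean <- mean(s$rate[bin == 0])
    for (b in sort(unique(bin))) {
      in_b <- bin == b
      n_y <- sum(in_b)
      if (n_y < min_coverage * period_length) next
      rows[[length(rows) + 1]] <- data.frame(
        s[1, KEY_COLS],
        period = period_label(min(s$year[in_b]), max(s$year[in_b])),
        years_in_period = n_y,
        mean_rate = mean(s$rate[in_b]),
        prr = mean(s$rate[in_b]) / ref_mean,
        prr_low = mean(s$rate_lower[in_b]) / ref_mean,
        prr_high = mean(s$rate_upper[in_b]) / ref_mean,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
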
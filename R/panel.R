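# Central long-format container: one row per (measure, location, sex,
# age band, year) carrying the rate (per 100,000), the count, and 95%
# uncertainty bounds on both metrics.

# Rates are stored per 100,000 throughout; every conversion to per-person
# risks goes through this one constant.
RATE_SCALE <- 1e5

#' Ordered five-year age bands accepted in raw input
#'
#' The package analyses adults aged 70 and over in the six five-year bands
#' used by GBD results extracts. The label `"70+"` denotes the all-ages-70+
#' aggregate and is only produced by [aggregate_strata()] (or trusted from
#' input that already carries it).
#'
#' @return Character vector of band labels in ascending age order.
#' @export
age_bands <- function() {
  c("70-74", "75-79", "80-84", "85-89", "90-94", "95+")
}

AGE_AGG <- "70+"

all_age_levels <- function() c(age_bands(), AGE_AGG)

SDI_LEVELS <- c("low", "low-middle", "middle", "high-middle", "high", "none")
SEX_LEVELS <- c("Male", "Female", "Both")
MEASURE_LEVELS <- c("Deaths", "DALYs")

PANEL_COLS <- c(
  "measure", "location", "sdi_group", "sex", "age_band", "year",
  "rate", "count", "rate_lower", "rate_upper", "count_lower", "count_upper"
)

# stratum identity excluding year
KEY_COLS <- c("measure", "location", "sdi_group", "sex", "age_band")

#' Construct a validated burden panel
#'
#' Assembles long-format burden observations into a `burden_panel`, a tibble
#' with one row per stratum-year. Validation enforces the panel invariants:
#' recognised factor labels, at most one row per (key, year), gap-free year
#' sequences within each stratum, non-negative rates and counts, and bound
#' ordering `lower <= value <= upper` wherever bounds are present.
#'
#' @param data Data frame with columns `measure`, `location`, `sdi_group`,
#'   `sex`, `age_band`, `year`, `rate`, `count` and optionally
#'   `rate_lower`, `rate_upper`, `count_lower`, `count_upper` (missing bound
#'   columns are filled with `NA`).
#' @param source Character label recorded in the panel's metadata.
#' @return A `burden_panel` tibble ordered by key and year.
#' @export
burden_panel <- function(data, source = "unspecified") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in setdiff(PANEL_COLS, names(data))) {
    if (!col %in% c("rate_lower", "rate_upper", "count_lower", "count_upper")) {
      stop("burden_panel: missing required column '", col, "'", call. = FALSE)
    }
    data[[col]] <- NA_real_
  }
  data <- data[PANEL_COLS]
  data$year <- as.integer(data$year)

  bad_band <- setdiff(unique(data$age_band), all_age_levels())
  if (length(bad_band) > 0) {
    stop("burden_panel: unrecognised age band(s): ",
         paste(bad_band, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(data$sex), SEX_LEVELS)
  if (length(bad_sex) > 0) {
    stop("burden_panel: unrecognised sex label(s): ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  bad_measure <- setdiff(unique(data$measure), MEASURE_LEVELS)
  if (length(bad_measure) > 0) {
    stop("burden_panel: unrecognised measure(s): ",
         paste(bad_measure, collapse = ", "), call. = FALSE)
  }
  bad_sdi <- setdiff(unique(data$sdi_group), SDI_LEVELS)
  if (length(bad_sdi) > 0) {
    stop("burden_panel: unrecognised sdi_group(s): ",
         paste(bad_sdi, collapse = ", "), call. = FALSE)
  }

  key <- panel_key(data)
  if (anyDuplicated(paste(key, data$year))) {
    dup <- paste(key, data$year)[duplicated(paste(key, data$year))]
    stop("burden_panel: duplicate observation(s) for ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }

  for (s in split(data, key)) {
    yrs <- sort(s$year)
    if (length(yrs) > 1 && !all(diff(yrs) == 1L)) {
      stop("burden_panel: year sequence has gaps in stratum ",
           panel_key(s[1, ]), call. = FALSE)
    }
  }

  neg <- which(data$rate < 0 | data$count < 0)
  if (length(neg) > 0) {
    stop("burden_panel: negative rate or count in row(s) ",
         paste(head(neg, 5), collapse = ", "), call. = FALSE)
  }

  check_bounds <- function(lo, val, hi, what) {
    ok <- is.na(lo) | is.na(hi) | (lo <= val + 1e-9 & val <= hi + 1e-9)
    if (!all(ok, na.rm = TRUE)) {
      stop("burden_panel: ", what, " bounds do not bracket the point value ",
           "in row(s) ", paste(head(which(!ok), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  check_bounds(data$rate_lower, data$rate, data$rate_upper, "rate")
  check_bounds(data$count_lower, data$count, data$count_upper, "count")

  ord <- order(data$measure, data$location, data$sex,
               match(data$age_band, all_age_levels()), data$year)
  data <- data[ord, , drop = FALSE]
  out <- tibble::as_tibble(data)
  class(out) <- c("burden_panel", class(out))
  attr(out, "source") <- source
  out
}

panel_key <- function(df) {
  do.call(paste, c(df[KEY_COLS], sep = "|"))
}

#' Test whether an object is a burden panel
#' @param x Object.
#' @return Logical scalar.
#' @export
is_burden_panel <- function(x) inherits(x, "burden_panel")

# keep the class when a panel is subset by rows
#' @export
`[.burden_panel` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(PANEL_COLS %in% names(out))) {
    class(out) <- unique(c("burden_panel", class(out)))
    attr(out, "source") <- attr(x, "source")
  }
  out
}

# Map a location label to its SDI quintile group. SDI itself is an input
# label, never computed here.
sdi_from_location <- function(location) {
  map <- c("Low SDI" = "low", "Low-middle SDI" = "low-middle",
           "Middle SDI" = "middle", "High-middle SDI" = "high-middle",
           "High SDI" = "high")
  out <- unname(map[location])
  out[is.na(out)] <- "none"
  out
}

# Extract one stratum's (year, rate) series as a plain data.frame.
stratum_series <- function(panel, measure = NULL, location = NULL,
                           sex = NULL, age_band = NULL) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(measure))  keep <- keep & panel$measure == measure
  if (!is.null(location)) keep <- keep & panel$location == location
  if (!is.null(sex))      keep <- keep & panel$sex == sex
  if (!is.null(age_band)) keep <- keep & panel$age_band == age_band
  out <- as.data.frame(panel[keep, , drop = FALSE])
  out[order(out$year), , drop = FALSE]
}
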
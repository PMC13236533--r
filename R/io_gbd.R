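# Ingestion and summarisation of GBD-results-dialect CSV extracts:
# columns measure_name, location_name, sex_name, age_name, cause_name,
# rei_name, metric_name, year, val, upper, lower with metric_name in
# {"Rate", "Number"}. Rate and Number rows for the same stratum-year are
# merged into one observation.

GBD_COLS <- c("measure_name", "location_name", "sex_name", "age_name",
              "cause_name", "rei_name", "metric_name", "year",
              "val", "upper", "lower")

gbd_age_label <- function(band) {
  ifelse(band == AGE_AGG, "70+ years", paste(band, "years"))
}

band_from_gbd_age <- function(age_name) {
  x <- sub(" years$", "", trimws(age_name))
  x[x == "70 plus"] <- AGE_AGG
  x
}

#' Read a GBD results CSV extract into a burden panel
#'
#' Parses a CSV in the GBD Results tool dialect and merges the `Rate` and
#' `Number` rows for each stratum-year into single observations carrying
#' both metrics with their 95% uncertainty bounds. The SDI quintile group is
#' derived from the location label (e.g. `"High-middle SDI"`); all other
#' locations get `sdi_group = "none"`.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default) any age band outside the six 70+
#'   five-year bands (or the `"70+ years"` aggregate) is an error naming the
#'   offending band; if `FALSE` such rows are dropped with a message.
#' @return A [burden_panel()].
#' @export
read_gbd_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("read_gbd_csv: file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(GBD_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_gbd_csv: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(v))
    if (length(bad) > 0) {
      stop("read_gbd_csv: non-numeric '", col, "' in data row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    v
  }
  raw$val <- num("val"); raw$upper <- num("upper"); raw$lower <- num("lower")
  raw$year <- as.integer(num("year"))

  raw$age_band <- band_from_gbd_age(raw$age_name)
  outside <- !(raw$age_band %in% all_age_levels())
  if (any(outside)) {
    bad_bands <- unique(raw$age_name[outside])
    if (strict) {
      stop("read_gbd_csv: age band(s) outside the 70+ scope: ",
           paste(bad_bands, collapse = ", "),
           " (use strict = FALSE to drop them)", call. = FALSE)
    }
    message("read_gbd_csv: dropping ", sum(outside),
            " row(s) with out-of-scope age band(s): ",
            paste(bad_bands, collapse = ", "))
    raw <- raw[!outside, , drop = FALSE]
  }

  bad_metric <- setdiff(unique(raw$metric_name), c("Rate", "Number"))
  if (length(bad_metric) > 0) {
    stop("read_gbd_csv: unrecognised metric_name: ",
         paste(bad_metric, collapse = ", "), call. = FALSE)
  }

  kid <- paste(raw$measure_name, raw$location_name, raw$sex_name,
               raw$age_band, raw$year, raw$metric_name, sep = "|")
  if (anyDuplicated(kid)) {
    stop("read_gbd_csv: duplicate (stratum, year, metric) row(s): ",
         paste(unique(kid[duplicated(kid)])[1:min(3, sum(duplicated(kid)))],
               collapse = "; "), call. = FALSE)
  }

  base_key <- c("measure_name", "location_name", "sex_name", "age_band", "year")
  take <- function(metric, prefix) {
    rows <- raw[raw$metric_name == metric, , drop = FALSE]
    out <- rows[base_key]
    out[[prefix]] <- rows$val
    out[[paste0(prefix, "_lower")]] <- rows$lower
    out[[paste0(prefix, "_upper")]] <- rows$upper
    out
  }
  merged <- merge(take("Rate", "rate"), take("Number", "count"),
                  by = base_key, all = TRUE)

  burden_panel(data.frame(
    measure = merged$measure_name,
    location = merged$location_name,
    sdi_group = sdi_from_location(merged$location_name),
    sex = merged$sex_name,
    age_band = merged$age_band,
    year = merged$year,
    rate = merged$rate,
    count = merged$count,
    rate_lower = merged$rate_lower,
    rate_upper = merged$rate_upper,
    count_lower = merged$count_lower,
    count_upper = merged$count_upper,
    stringsAsFactors = FALSE
  ), source = path)
}

#' Write a burden panel as a GBD results CSV
#'
#' Emits the exact dialect read by [read_gbd_csv()]: one `Rate` and one
#' `Number` row per observation, with full double precision so that a
#' write/read round trip reproduces the panel.
#'
#' @param panel A [burden_panel()].
#' @param path Output file path.
#' @param cause_name,rei_name Labels written into the cause and risk columns.
#' @return Invisibly, `path`.
#' @export
write_gbd_csv <- function(panel, path,
                          cause_name = "Ischemic stroke",
                          rei_name = "High body-mass index") {
  stopifnot(is_burden_panel(panel))
  p <- as.data.frame(panel)
  one_metric <- function(metric, val, lower, upper) {
    data.frame(
      measure_name = p$measure, location_name = p$location,
      sex_name = p$sex, age_name = gbd_age_label(p$age_band),
      cause_name = cause_name, rei_name = rei_name,
      metric_name = metric, year = p$year,
      val = val, upper = upper, lower = lower,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    one_metric("Rate", p$rate, p$rate_lower, p$rate_upper),
    one_metric("Number", p$count, p$count_lower, p$count_upper)
  )
  out <- out[!is.na(out$val), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Reconstruct the population denominator from a rate and a count
#'
#' GBD extracts report rates per 100,000 and counts; the implied population
#' is `count / rate * 100000`. This identity is the backbone of stratum
#' aggregation, the demographic decomposition and population projection.
#'
#' @param rate Rate per 100,000 person-years; must be strictly positive.
#' @param count Event count (deaths or DALYs); non-negative.
#' @return Population in persons (vectorised).
#' @export
reconstruct_population <- function(rate, count) {
  if (any(is.na(rate)) || any(rate <= 0)) {
    stop("reconstruct_population: rate must be > 0 (population undefined)",
         call. = FALSE)
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop("reconstruct_population: count must be >= 0", call. = FALSE)
  }
  count / rate * RATE_SCALE
}

#' Aggregate panel strata over sex and/or age band
#'
#' Collapses strata by summing counts and reconstructed populations, so the
#' aggregated rate is the population-weighted stratum rate
#' (total count / total population x 100,000). Uncertainty bounds are summed
#' on the count scale and divided by the total population — a conservative
#' perfect-dependence approximation, since draw-level propagation is not
#' available outside the GBD machinery.
#'
#' @param panel A [burden_panel()] in which every collapsed stratum-year has
#'   both a rate and a count.
#' @param collapse Character subset of `c("sex", "age_band")` naming the key
#'   dimensions to collapse.
#' @return A [burden_panel()] with `sex = "Both"` and/or `age_band = "70+"`
#'   in the collapsed dimensions.
#' @export
aggregate_strata <- function(panel, collapse = c("sex", "age_band")) {
  stopifnot(is_burden_panel(panel))
  collapse <- match.arg(collapse, c("sex", "age_band"), several.ok = TRUE)
  p <- as.data.frame(panel)

  missing_metric <- is.na(p$rate) | is.na(p$count) | p$rate <= 0
  if (any(missing_metric)) {
    off <- unique(paste(panel_key(p), p$year)[missing_metric])
    stop("aggregate_strata: rate and count both required to reconstruct ",
         "population; offending stratum-years: ",
         paste(head(off, 5), collapse = "; "), call. = FALSE)
  }

  p$population <- reconstruct_population(p$rate, p$count)
  if ("sex" %in% collapse) p$sex <- "Both"
  if ("age_band" %in% collapse) p$age_band <- AGE_AGG

  grp <- paste(panel_key(p), p$year, sep = "|")
  agg <- function(col) as.numeric(tapply(p[[col]], grp, sum))
  first <- function(col) as.vector(tapply(p[[col]], grp, `[`, 1))
  count <- agg("count")
  pop <- agg("population")
  count_lower <- agg("count_lower")
  count_upper <- agg("count_upper")

  burden_panel(data.frame(
    measure = first("measure"), location = first("location"),
    sdi_group = first("sdi_group"), sex = first("sex"),
    age_band = first("age_band"),
    year = as.integer(as.numeric(tapply(p$year, grp, `[`, 1))),
    rate = count / pop * RATE_SCALE,
    count = count,
    rate_lower = count_lower / pop * RATE_SCALE,
    rate_upper = count_upper / pop * RATE_SCALE,
    count_lower = count_lower,
    count_upper = count_upper,
    stringsAsFactors = FALSE
  ), source = paste0(attr(panel, "source"), " [aggregated]"))
}

#' Population-attributable fraction from attributable and total-cause panels
#'
#' Divides the risk-attributable burden by the total-cause burden for each
#' matching stratum-year: `paf = attributable / total x 100`. Computed on
#' counts by default; `on = "rate"` is equivalent when both panels describe
#' exactly the same strata (same denominators).
#'
#' @param attributable Panel of risk-attributable burden.
#' @param total_cause Panel of total-cause burden with identical keys/years.
#' @param on `"count"` (default) or `"rate"`.
#' @return Tibble with the stratum key columns, `year` and `paf` in percent.
#' @export
compute_paf <- function(attributable, total_cause, on = c("count", "rate")) {
  stopifnot(is_burden_panel(attributable), is_burden_panel(total_cause))
  on <- match.arg(on)
  a <- as.data.frame(attributable)
  t_ <- as.data.frame(total_cause)
  a$.k <- paste(panel_key(a), a$year)
  t_$.k <- paste(panel_key(t_), t_$year)
  unmatched <- setdiff(a$.k, t_$.k)
  if (length(unmatched) > 0) {
    stop("compute_paf: stratum-years missing from total_cause panel: ",
         paste(head(unmatched, 5), collapse = "; "), call. = FALSE)
  }
  idx <- match(a$.k, t_$.k)
  av <- a[[on]]
  tv <- t_[[on]][idx]
  if (any(tv == 0 & av > 0)) {
    stop("compute_paf: total burden is zero where attributable burden is ",
         "positive", call. = FALSE)
  }
  paf <- ifelse(av == 0, 0, av / tv * 100)
  tibble::as_tibble(cbind(a[c(KEY_COLS, "year")],
                          data.frame(paf = paf)))
}

#' DALY-to-death rate ratio by location
#'
#' For each location's 70+ aggregate, divides the DALY rate by the death
#' rate. The ratio summarises healthy life lost per death; the unweighted
#' mean across locations is returned as an attribute and printed by the
#' summary.
#'
#' @param panel Panel containing both `DALYs` and `Deaths` rates for each
#'   location (70+ aggregate rows, `sex = "Both"` preferred when present).
#' @param year Calendar year to summarise (default: latest shared year).
#' @return Tibble `(location, daly_rate, death_rate, ratio)` with attribute
#'   `mean_ratio`.
#' @export
daly_death_ratio <- function(panel, year = NULL) {
  stopifnot(is_burden_panel(panel))
  p <- as.data.frame(panel)
  p <- p[p$age_band == AGE_AGG, , drop = FALSE]
  if (nrow(p) == 0) {
    stop("daly_death_ratio: panel has no 70+ aggregate rows; call ",
         "aggregate_strata() first", call. = FALSE)
  }
  if ("Both" %in% p$sex) p <- p[p$sex == "Both", , drop = FALSE]
  if (is.null(year)) year <- max(p$year)
  p <- p[p$year == year, , drop = FALSE]

  locs <- sort(unique(p$location))
  daly <- p$rate[match(paste(locs, "DALYs"), paste(p$location, p$measure))]
  death <- p$rate[match(paste(locs, "Deaths"), paste(p$location, p$measure))]
  ok <- !is.na(daly) & !is.na(death)
  zero <- ok & death == 0
  if (any(zero)) {
    warning("daly_death_ratio: zero death rate in ",
            paste(locs[zero], collapse = ", "),
            "; excluded from the mean")
  }
  out <- tibble::tibble(
    location = locs[ok], daly_rate = daly[ok], death_rate = death[ok],
    ratio = ifelse(death[ok] == 0, NA_real_, daly[ok] / death[ok])
  )
  attr(out, "mean_ratio") <- mean(out$ratio, na.rm = TRUE)
  attr(out, "year") <- year
  out
}
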
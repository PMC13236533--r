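# Shapley three-factor decomposition of a change in death counts.
# The value function factors deaths as D = N * sum_a c_a * m_a with
# N = total population 70+, c = age(-sex) share vector, m = age(-sex)
# specific death risks (per person-year). Each factor's contribution is
# the average over all 3! switching orders of its marginal effect —
# additive and order-invariant by construction.

#' Construct a demographic state
#'
#' A demographic state captures everything the decomposition needs at one
#' time point: the total population `N`, the composition shares `c` over
#' cells (age bands, or sex-by-age cells), and the cell-specific death
#' risks `m` in deaths per person-year.
#'
#' @param year Calendar year of the state.
#' @param N Total population (persons, ages 70+ within the stratum).
#' @param shares Named non-negative vector summing to 1.
#' @param risks Named non-negative vector, same cells as `shares`, deaths
#'   per person-year.
#' @param sex Sex stratum label.
#' @return A `demographic_state`.
#' @export
demographic_state <- function(year, N, shares, risks, sex = "Both") {
  if (is.null(names(shares)) || is.null(names(risks)) ||
      !identical(sort(names(shares)), sort(names(risks)))) {
    stop("demographic_state: shares and risks must share cell names",
         call. = FALSE)
  }
  risks <- risks[names(shares)]
  if (abs(sum(shares) - 1) > 1e-12) {
    stop("demographic_state: shares must sum to 1 (got ",
         format(sum(shares)), ")", call. = FALSE)
  }
  if (any(shares < 0) || any(risks < 0) || N < 0) {
    stop("demographic_state: N, shares and risks must be non-negative",
         call. = FALSE)
  }
  structure(list(year = as.integer(year), N = N, shares = shares,
                 risks = risks, sex = sex),
            class = "demographic_state")
}

#' @export
print.demographic_state <- function(x, ...) {
  cat(sprintf("Demographic state %d (%s): N = %s, %d cells, implied deaths %.1f\n",
              x$year, x$sex, format(x$N, big.mark = ","),
              length(x$shares), implied_deaths(x)))
  invisible(x)
}

#' Deaths implied by a demographic state
#' @param state A [demographic_state()].
#' @return `N * sum(shares * risks)`.
#' @export
implied_deaths <- function(state) {
  state$N * sum(state$shares * state$risks)
}

#' Build a demographic state from a burden panel
#'
#' Reconstructs cell populations from rates and counts for one year, then
#' forms the total, the composition shares and the per-person risks. For
#' `sex = "Both"` with `structure = "age_sex"` (the default when Male and
#' Female rows are available) the twelve sex-by-age cells are used, so the
#' "aging" factor captures shifts in both age and sex composition; with
#' `structure = "age"` the six pooled both-sex age bands are used.
#'
#' @param panel A [burden_panel()].
#' @param year Calendar year.
#' @param sex `"Male"`, `"Female"` or `"Both"`.
#' @param measure Measure, default `"Deaths"`.
#' @param location Optional location filter (needed if the panel holds
#'   several locations).
#' @param structure `"age_sex"` or `"age"`; only relevant for
#'   `sex = "Both"`.
#' @return A [demographic_state()].
#' @export
state_from_panel <- function(panel, year, sex, measure = "Deaths",
                             location = NULL,
                             structure = c("age_sex", "age")) {
  stopifnot(is_burden_panel(panel))
  structure <- match.arg(structure)
  p <- as.data.frame(panel)
  p <- p[p$measure == measure & p$year == year &
           p$age_band %in% age_bands(), , drop = FALSE]
  if (!is.null(location)) p <- p[p$location == location, , drop = FALSE]
  if (length(unique(p$location)) > 1) {
    stop("state_from_panel: several locations in panel; pass `location`",
         call. = FALSE)
  }

  if (sex == "Both" && structure == "age_sex" &&
      all(c("Male", "Female") %in% p$sex)) {
    p <- p[p$sex %in% c("Male", "Female"), , drop = FALSE]
    cell <- paste(p$sex, p$age_band, sep = ":")
    expected <- as.vector(outer(c("Male", "Female"), age_bands(),
                                paste, sep = ":"))
  } else {
    p <- p[p$sex == sex, , drop = FALSE]
    cell <- p$age_band
    expected <- age_bands()
  }
  missing_cells <- setdiff(expected, cell)
  if (length(missing_cells) > 0) {
    stop("state_from_panel: missing cell(s) for ", sex, " ", year, ": ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  }

  pop <- reconstruct_population(p$rate, p$count)
  names(pop) <- cell
  risks <- p$rate / RATE_SCALE
  names(risks) <- cell
  pop <- pop[expected]; risks <- risks[expected]
  demographic_state(year, sum(pop), pop / sum(pop), risks, sex = sex)
}

#' Counterfactual deaths mixing factors from different states
#'
#' The decomposition's value function evaluated with the population size
#' from one state, the composition from another and the risks from a
#' third: `N_i * sum_a c_{j,a} * m_{k,a}`.
#'
#' @param state_N,state_c,state_m States supplying `N`, shares and risks.
#' @return Deaths under the mixed configuration.
#' @export
counterfactual_deaths <- function(state_N, state_c, state_m) {
  cells <- names(state_c$shares)
  if (!identical(sort(cells), sort(names(state_m$risks)))) {
    stop("counterfactual_deaths: states have different cell sets",
         call. = FALSE)
  }
  state_N$N * sum(state_c$shares * state_m$risks[cells])
}

#' Shapley decomposition of a death-count change into three factors
#'
#' Decomposes `D(final) - D(base)` into the contributions of population
#' growth (N), population aging / composition (c) and age-specific rate
#' change (m). Each contribution is the average over all six factor
#' switching orders of the marginal change when that factor moves from its
#' base to its final value; the three contributions sum to the total change
#' exactly, and a factor identical in both states contributes exactly zero.
#' The permutations are enumerated directly rather than using the
#' closed-form three-factor expression.
#'
#' @param base,final [demographic_state()] objects with the same cells.
#' @param baseline_mode Label recording how the base state was obtained:
#'   `"descriptive"` (observed values) or `"model_fitted"` (fitted values
#'   from the projection model, for internal consistency with forecasts).
#' @return A `decomposition_result`: `delta_total`, `contrib_growth`,
#'   `contrib_aging`, `contrib_rate`, `baseline_mode`, `sex`, `years`.
#' @export
shapley_decompose <- function(base, final,
                              baseline_mode = c("descriptive", "model_fitted")) {
  stopifnot(inherits(base, "demographic_state"),
            inherits(final, "demographic_state"))
  baseline_mode <- match.arg(baseline_mode)
  if (!identical(sort(names(base$shares)), sort(names(final$shares)))) {
    stop("shapley_decompose: states have different cell sets", call. = FALSE)
  }

  value <- function(switched) {
    pick <- function(f) if (f %in% switched) final else base
    counterfactual_deaths(pick("N"), pick("c"), pick("m"))
  }

  factors <- c("N", "c", "m")
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  contrib <- c(N = 0, c = 0, m = 0)
  for (p in perms) {
    switched <- character(0)
    for (idx in p) {
      f <- factors[idx]
      before <- value(switched)
      switched <- c(switched, f)
      contrib[f] <- contrib[f] + (value(switched) - before)
    }
  }
  contrib <- contrib / length(perms)

  out <- list(
    delta_total = implied_deaths(final) - implied_deaths(base),
    contrib_growth = unname(contrib["N"]),
    contrib_aging = unname(contrib["c"]),
    contrib_rate = unname(contrib["m"]),
    baseline_mode = baseline_mode,
    sex = base$sex,
    years = c(base$year, final$year)
  )
  class(out) <- "decomposition_result"
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("Change in deaths %d -> %d (%s, %s baseline): %+.0f\n",
              x$years[1], x$years[2], x$sex, x$baseline_mode, x$delta_total))
  cat(sprintf("  population growth %+.0f\n  population aging  %+.0f\n  rate change       %+.0f\n",
              x$contrib_growth, x$contrib_aging, x$contrib_rate))
  invisible(x)
}

#' Share of the demographic increase offset by rate improvement
#'
#' When population growth plus aging push deaths up and rate change pulls
#' them down, returns how much of the demographic-driven increase the rate
#' decline counteracts: `|contrib_rate| / (contrib_growth + contrib_aging)
#' * 100`.
#'
#' @param result A `decomposition_result` with positive demographic sum and
#'   non-positive rate contribution.
#' @return Percentage offset.
#' @export
offset_fraction <- function(result) {
  stopifnot(inherits(result, "decomposition_result"))
  demo <- result$contrib_growth + result$contrib_aging
  if (demo <= 0) {
    stop("offset_fraction: demographic contribution sum must be > 0",
         call. = FALSE)
  }
  if (result$contrib_rate > 0) {
    stop("offset_fraction: rate contribution must be <= 0", call. = FALSE)
  }
  abs(result$contrib_rate) / demo * 100
}
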
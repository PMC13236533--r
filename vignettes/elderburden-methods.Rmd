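---
title: "Methods: trend segmentation, decomposition and projection of burden in adults 70+"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend segmentation, decomposition and projection of burden in adults 70+}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elderburden)
```

## Scope and data model

`elderburden` analyses burden-of-disease panels for adults aged 70 and
over: annual deaths and DALYs attributable to a risk factor, reported as
rates per 100,000 and counts with 95% uncertainty intervals, stratified by
sex, five-year age band (70–74 … 95+) and location or SDI quintile, in the
CSV dialect of the GBD Results tool. The central container is the
`burden_panel`, a validated long-format tibble with one row per
stratum-year carrying both metrics and their bounds. Validation enforces
recognised labels, uniqueness per (key, year), gap-free year sequences and
bound ordering. SDI is treated purely as a supplied grouping label; the
package never computes it.

Populations are never taken from an external source: the denominator of a
rate-and-count pair is reconstructed as `count / rate * 100000`. This
identity is exact for GBD-style extracts and is the backbone of
aggregation, decomposition and projection. Aggregation over sex and/or age
sums counts and reconstructed populations, so the aggregate rate is the
population-weighted stratum rate. Uncertainty bounds are aggregated by
summing on the count scale (perfect dependence). This is a deliberate,
conservative approximation: proper propagation requires draw-level
posterior samples that only the original estimation machinery has, and
summing bounds can only over-state the aggregate interval. Users needing
an independence assumption can switch projection-interval aggregation to
root-sum-square (`bounds = "rss"`).

## Trend segmentation and annual percent change

Within each stratum the annual rate is modelled on the log scale. A
single-segment fit is OLS of `ln(rate)` on calendar year; the annual
percent change is `APC = (exp(beta) - 1) * 100` with a 95% interval from
`beta ± 1.96 SE`. Standard errors are Newey–West
(heteroskedasticity- and autocorrelation-consistent, Bartlett kernel,
maximum lag 1, with the n/(n−k) small-sample correction) — annual rate
series from modelled estimates are smooth, so neighbouring residuals are
positively correlated and plain OLS standard errors would be optimistic.

Segmented trends allow 1–6 segments with breakpoints constrained to
integer years and a minimum segment span of 5 years (boundary-year
difference). Because a ≤32-year series admits only a few thousand
admissible breakpoint configurations, the search is exhaustive: for every
candidate segment count the continuous piecewise-linear model (hinge basis,
continuity enforced at breakpoints) is fitted by OLS at every admissible
breakpoint set, and the best residual sum of squares per segment count
enters the BIC

    BIC(k) = n ln(RSS/n) + p ln(n),  p = (#slopes) + (#breakpoints) + 1,

with ties broken toward fewer segments. Exhaustive search makes the
selected optimum exact rather than a local solution of a continuous
optimiser. Two numerical conventions matter: the RSS is floored at
`n * 1e-20` so that numerically perfect fits (noiseless data) are compared
by parameter count alone, and rates of exactly zero are an error rather
than being floored — 70+ burden extracts should not contain them, and
silent flooring would corrupt the log-scale fit.

Per-segment APC point estimates are taken from the constrained piecewise
fit (slopes are cumulative sums of the hinge coefficients); their standard
errors come from Newey–West inference on per-segment OLS refits. The two
coincide when continuity binds loosely; where they differ, the refit SE is
the honest dispersion measure for that segment's own years. The
full-period AAPC is a separate single log-linear fit over all years —
never a weighted average of segment APCs, so it answers "what was the
average pace over the whole period" on its own terms.

Period rate ratios are purely descriptive: annual point rates are averaged
within consecutive 5-year calendar bins and divided by the first
(reference) bin's mean; a partial terminal bin is kept and labelled by its
actual span (1990–2021 ends with a two-year "2020–2021" bin). Bound ratios
divide the bin's mean lower/upper estimates by the reference *point* mean —
an asymmetric rule that summarises the reported ribbons and must not be
read as an inferential confidence interval.

## Shapley three-factor decomposition

The change in deaths between two years is decomposed with the value
function

    D = N * sum_a c_a * m_a,

where `N` is the total 70+ population, `c` the composition shares and `m`
the cell-specific death risks. This standard multiplicative factorisation
is the package's modelling choice for the three factors "population
growth, population aging, age-specific rate change". Each factor's
contribution is the average, over all 3! orders of switching factors from
their base to their final values, of that factor's marginal effect on `D`.
The implementation enumerates the six permutations directly; the
closed-form three-factor Shapley expression exists only as an independent
test oracle. Additivity (contributions sum exactly to the total change),
symmetry and the dummy property (a factor identical in both states
contributes exactly zero) hold by construction and are verified
property-style over thousands of random states.

For both-sex decompositions the default composition vector has twelve
sex-by-age cells, so the "aging" factor absorbs shifts in both age and sex
structure; passing `structure = "age"` uses the six pooled both-sex bands
instead. The two conventions answer slightly different questions and give
different splits between aging and rates; the package reports per-sex and
both-sex decompositions separately and never sums per-sex contributions
into a pooled answer, because the pooled composition is not the sum of the
sex-specific ones.

Baselines are first-class: `descriptive` anchors the base state to the
observed panel values, while `model_fitted` anchors it to the projection
model's fitted values at the anchor year. The model-fitted baseline keeps
a projected-change decomposition internally consistent with the forecast
(the projected path starts from the fitted line, not from the observed
point); the descriptive baseline is the natural sensitivity analysis.

## Projection, hindcasting and robustness

Forecasts use empirical age-specific log-linear extrapolation, not an
age–period–cohort or Bayesian model: per age-sex stratum, independent OLS
fits to `ln(rate)` and `ln(population)` over a training window (default
2000–2021) are continued over the horizon (default 2022–2044). Rates carry
t-based 95% prediction intervals computed on the log scale (variance
`s² (1 + 1/n + (x₀-x̄)²/Sxx)`, n−2 degrees of freedom) and exponentiated;
populations are point paths, so count uncertainty reflects rate
uncertainty only — a documented simplification, since the reconstruction
identity makes population a deterministic transform of the reported
metrics. Stratum counts are `rate × population / 1e5`; aggregates sum
counts and populations, and aggregate bounds are stratum-bound sums by
default (RSS behind a flag, as above).

Hindcasting reuses the same machinery with an earlier window: train on
2000–2014, score 2015–2021 with MAPE, MAE, RMSE on the natural rate scale
and the share of test years inside the 95% prediction interval. On data
generated from the model family with zero noise all errors are exactly
zero and coverage is 100%; under lognormal noise at σ = 0.02 stratum-level
coverage is near nominal. A caveat the synthetic experiments make visible:
when the underlying trend bends (multiple segments) or the aggregate's age
composition drifts, a log-linear hindcast of the *aggregate* series is
misspecified — point errors stay moderate but interval coverage degrades
badly. Stratum-level projection plus aggregation is therefore the primary
design, and aggregate-series hindcast coverage should be read as a
misspecification diagnostic rather than a calibration guarantee.

Robustness compares the primary forecast of an aggregated rate series with
two alternatives fitted on the log scale (positivity and comparability;
natural scale behind a flag): an unobserved-components model with local
linear trend (`stats::StructTS(type = "trend")`) and an ARIMA selected by
AIC over p, q ∈ {0, 1, 2}, d ∈ {0, 1}, each candidate including a mean
(d = 0) or drift (d = 1) term, with non-convergent candidates skipped. On
an exactly exponential series a random walk with drift on the log scale
reproduces the log-linear path, which the tests exploit as an
equivalence oracle. Divergence is summarised by the mean absolute
percentage difference over the horizon and the percentage difference at
the final year, both with the primary path as denominator (directional by
design).

## The synthetic generator as study conditions

`synthetic_spec()` fixes the conditions under which the pipeline is
exercised and tested; its defaults are not tuning knobs. The default panel
has twelve strata (two sexes × six bands) over 1990–2021 with: baseline
death rates rising steeply with age (13 to 148 per 100,000 at the band
midpoints, ±10% by sex) — chosen so the 1990 global total is in the tens
of thousands of deaths, matching the scale of a single-risk single-cause
burden in this age group; a three-segment rate trend (near-flat to 2001,
−2.85%/yr to 2012, −1.71%/yr after) mirroring the global trajectory of
this burden; exponential population growth of 2.8–3.8%/yr with the oldest
bands fastest, so age structure shifts upward as in real elderly
populations; multiplicative lognormal rate noise σ = 0.02 (GBD point
series are smooth); and symmetric ±80% uncertainty ribbons, reflecting the
very wide intervals typical of risk-attributable estimates. Noise applies
to rates only; counts inherit it multiplicatively and populations are
noiseless, matching the treatment of population as a deterministically
reconstructed denominator. Per-stratum random draws use child seeds
derived by a stable string hash of the stratum key, so adding a stratum
never perturbs existing draws.

What the generator does not emulate: draw-based asymmetric uncertainty,
spatial correlation between locations, covariate-driven estimation and
non-log-linear trend shapes. Passing tests therefore demonstrate the
correctness of the implemented procedures under the stated data-generating
process, not the epidemiological validity of any particular real-world
extract.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data at
the scale of the real design: 32-year series, 12 strata, 23-year horizons;
stochastic properties use 200-replicate batches (slope-CI recovery,
hindcast coverage) and 1000 random states (decomposition properties).
Breakpoint search spaces are enumerated exactly (a few hundred to a few
thousand OLS fits per series). Degenerate inputs are errors, not silent
repairs: non-positive rates anywhere on a log scale, overlapping
train/test windows, missing age bands in a state, and aggregation without
both metrics all fail with named messages.

## Worked example

```{r example, eval = FALSE}
g <- generate_panel(synthetic_spec(seed = 7))
panel <- g$panel

agg <- aggregate_strata(panel)                  # both-sex, 70+ aggregate
s <- as.data.frame(agg)
fit_segmented(s$year, s$rate)                   # joinpoints, APCs, AAPC

d <- shapley_decompose(state_from_panel(panel, 1990, "Both"),
                       state_from_panel(panel, 2021, "Both"))
d
offset_fraction(d)

proj <- project_aggregate(panel)                # 2022-2044 forecast
proj
hindcast(s$year, s$rate)                        # 2000-2014 / 2015-2021
```

## Known limitations

Bound aggregation and count-scale prediction intervals are conservative
approximations, documented above. Segment standard errors from per-segment
refits differ in principle from those of the constrained joint fit's
covariance; the refit choice is simple and transparent but slightly
conservative near tightly binding breakpoints. PAF recomputation divides
attributable by total-cause burden and cannot distinguish whether a
published PAF was taken directly from source output or recomputed. The
descriptive period-rate-ratio bounds are not confidence intervals. The
projection model deliberately excludes cohort effects and external
population forecasts.
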
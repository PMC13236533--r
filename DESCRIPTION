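Package: elderburden
Title: Trend, Decomposition and Projection Analysis of Disease Burden in Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing Global Burden of Disease style burden panels
    (deaths and DALYs by five-year age band, sex and location) in adults aged
    seventy and over. Implements segmented log-linear trend models with
    BIC-selected integer-year breakpoints and Newey-West robust annual percent
    change inference, descriptive period rate ratios, a Shapley three-factor
    decomposition of death-count change into population growth, population
    aging and age-specific rate change, age-specific log-linear projection of
    rates and populations with prediction intervals, hindcast validation
    (MAPE, MAE, RMSE, interval coverage) and robustness comparison against
    structural time-series and ARIMA alternatives, plus population-attributable
    fraction and DALY-to-death summaries. A synthetic panel generator with
    known piecewise log-linear ground truth makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
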
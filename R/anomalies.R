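#' Per-calendar-month climatology of a daily series
#'
#' Value `m` is the mean over all days of the record falling in calendar
#' month `m`, ignoring missing days.  A month with no valid day yields `NA`
#' (its anomalies are masked downstream).
#'
#' @param dates vector of `Date`s (consecutive daily steps).
#' @param values numeric series aligned with `dates`; `NA` marks missing.
#' @return numeric vector of length 12 (January..December).
#' @export
monthly_climatology <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  mo <- month_of(dates)
  out <- rep(NA_real_, 12)
  means <- tapply(values, mo, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  out[as.integer(names(means))] <- as.numeric(means)
  out
}

#' LOWESS long-term trend of a daily series
#'
#' Locally weighted linear regression (tricube weights) on the time axis in
#' days since the series start.  `frac` is the fraction of the series
#' entering each local neighborhood (default 0.4, suited to slow non-linear
#' trends).  Missing days are excluded from the fit; the trend is still
#' evaluated there by linear interpolation between fitted neighbors.
#'
#' @param dates vector of `Date`s.
#' @param values numeric series; `NA` marks missing.
#' @param frac neighborhood fraction in (0, 1].
#' @param iter number of robustness (bisquare reweighting) iterations;
#'   0 disables robustness and makes the smoother a pure local linear fit.
#' @param delta interpolation shortcut of the underlying smoother, in days;
#'   `NULL` uses 1% of the time range (fast, visually identical), 0 forces
#'   an exact local fit at every day.
#' @return numeric trend evaluated at every input date.
#' @export
lowess_trend <- function(dates, values, frac = 0.4, iter = 0L, delta = NULL) {
  stopifnot(length(dates) == length(values))
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  x <- as.numeric(dates - dates[1])
  ok <- is.finite(values)
  if (sum(ok) == 0) stop("all values are missing; no trend estimable")
  if (sum(ok) < 10) stop("need at least 10 valid points for a trend")
  if (is.null(delta)) delta <- 0.01 * diff(range(x[ok]))
  fit <- lowess(x[ok], values[ok], f = frac, iter = iter, delta = delta)
  approx(fit$x, fit$y, xout = x, rule = 2)$y
}

#' Daily anomalies: remove seasonality and long-term trend
#'
#' The seasonal (per-calendar-month climatology) and trend (LOWESS)
#' components are estimated jointly by backfitting: each pass re-estimates
#' the climatology on the detrended series and the trend on the
#' deseasonalized series.  A single pass is the naive
#' "climatology, then trend" subtraction; a second pass removes the
#' aliasing a long-term trend leaves in the monthly climatology (and vice
#' versa), which a one-shot removal cannot.  Afterwards the series is
#' re-centered by removing the per-calendar-month means of the residual,
#' so (absent missing data) every calendar month of the anomalies averages
#' exactly to zero.  `order = "trend_first"` fits the trend on the raw
#' series in the first pass instead.
#'
#' @inheritParams lowess_trend
#' @param order `"climatology_first"` (default) or `"trend_first"`:
#'   which component is estimated first in the opening pass.
#' @param passes number of backfitting passes (>= 1; default 2).
#' @return numeric anomaly series with attributes `climatology` (12 values)
#'   and `trend` (per-day trend removed).
#' @export
compute_anomalies <- function(dates, values, frac = 0.4, iter = 0L,
                              delta = NULL,
                              order = c("climatology_first", "trend_first"),
                              passes = 2L) {
  order <- match.arg(order)
  if (passes < 1) stop("passes must be >= 1")
  mo <- month_of(dates)
  n <- length(values)
  trend <- rep(0, n)
  clim <- rep(0, 12)
  if (order == "trend_first")
    trend <- lowess_trend(dates, values, frac = frac, iter = iter,
                          delta = delta)
  for (k in seq_len(passes)) {
    clim <- monthly_climatology(dates, values - trend)
    trend <- lowess_trend(dates, values - clim[mo], frac = frac,
                          iter = iter, delta = delta)
  }
  resid <- values - clim[mo] - trend
  recenter <- monthly_climatology(dates, resid)
  anom <- resid - recenter[mo]
  attr(anom, "climatology") <- clim
  attr(anom, "trend") <- trend
  anom
}
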
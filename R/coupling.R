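#' First-order partial correlation
#'
#' Correlation between `x` and `y` controlling for `z`:
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`, with `r` the
#' Pearson correlation over complete triples.  In the coupling statistic,
#' `x` is the soil-moisture anomaly at `t - lag`, `y` the VPD anomaly at
#' `t`, and `z` the VPD anomaly at `t - lag` (removing VPD persistence).
#'
#' Returns `NA` when fewer than `min_pairs` complete triples exist, when a
#' series is constant, or when a control correlation is +-1 (degenerate
#' denominator); the reason is attached as attribute `reason`.
#'
#' @param x,y,z equal-length numeric vectors.
#' @param min_pairs minimum number of complete triples.
#' @return partial correlation in `[-1, 1]`, or `NA`.
#' @export
partial_correlation <- function(x, y, z, min_pairs = 4L) {
  if (length(y) != length(x) || length(z) != length(x))
    stop("x, y and z must have equal length")
  ok <- complete.cases(x, y, z)
  if (sum(ok) < min_pairs)
    return(structure(NA_real_, reason = "too_few_pairs"))
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0)
    return(structure(NA_real_, reason = "zero_variance"))
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  if (den <= 1e-12)
    return(structure(NA_real_, reason = "degenerate_control"))
  max(-1, min(1, (r_xy - r_xz * r_yz) / sqrt(den)))
}

#' Daily SM-VPD coupling in a lagged moving window
#'
#' For each focal day, all days `t` of the surrounding `window` (centered,
#' truncated at the series edges) contribute the triple
#' `(SM(t - lag), VPD(t), VPD(t - lag))`; the coupling for the focal day is
#' the partial correlation of the window's triples.  Windows with fewer
#' than `min_pairs` valid triples are missing.
#'
#' @param sm_anom,vpd_anom daily anomaly series on the same date axis.
#' @param dates shared vector of `Date`s.
#' @param lag lag in days (the analysis uses 1, 7 or 14; default 7).
#' @param window moving-window length in days.
#' @param min_pairs minimum valid triples per window (default 24, i.e. 80%
#'   of a 30-day window, mirroring the monthly missing-data rule).
#' @return tibble with `date`, `pcor`, `n_pairs`, `lag`, `window`.
#' @export
rolling_coupling <- function(sm_anom, vpd_anom, dates, lag = 7L,
                             window = 30L, min_pairs = 24L) {
  if (length(sm_anom) != length(vpd_anom) ||
      length(sm_anom) != length(dates))
    stop("sm_anom, vpd_anom and dates must share one date axis")
  res <- rolling_pcor_cpp(as.numeric(sm_anom), as.numeric(vpd_anom),
                          as.integer(lag), as.integer(window),
                          as.integer(min_pairs))
  tibble::tibble(date = dates, pcor = res$pcor, n_pairs = res$n_pairs,
                 lag = as.integer(lag), window = as.integer(window))
}

#' Aggregate daily coupling to calendar months
#'
#' The monthly coupling is the arithmetic mean of the defined daily values;
#' a month is eligible only if the fraction of missing daily values is
#' strictly below `max_missing` (default 20%).
#'
#' @param daily tibble from [rolling_coupling()] (columns `date`, `pcor`).
#' @param max_missing maximum tolerated fraction of missing daily values.
#' @return tibble with `year_month`, `pcor_monthly`, `n_valid_days`,
#'   `frac_missing`, `eligible`.
#' @export
monthly_aggregate <- function(daily, max_missing = 0.2) {
  daily |>
    dplyr::mutate(year_month = year_month(.data$date)) |>
    dplyr::group_by(.data$year_month) |>
    dplyr::summarise(
      pcor_monthly = if (any(is.finite(.data$pcor)))
        mean(.data$pcor, na.rm = TRUE) else NA_real_,
      n_valid_days = sum(is.finite(.data$pcor)),
      frac_missing = mean(!is.finite(.data$pcor)),
      .groups = "drop") |>
    dplyr::mutate(eligible = .data$frac_missing < max_missing)
}

#' Growing-season and dry-anomaly filters on monthly coupling
#'
#' A month is retained iff it is eligible under the missing-data rule,
#' its mean temperature is not below `temp_threshold` (growing season;
#' exactly 5 degrees C is retained), and its mean soil-moisture anomaly is
#' negative.  Optionally, months with non-negative monthly coupling can be
#' dropped as well (off by default).
#'
#' @param monthly tibble from [monthly_aggregate()].
#' @param monthly_temperature tibble with `year_month`, `temperature`.
#' @param monthly_sm_anomaly tibble with `year_month`, `sm_anomaly`.
#' @param temp_threshold growing-season temperature threshold, degrees C.
#' @param require_negative_pcor additionally require `pcor_monthly < 0`.
#' @return `monthly` with `growing_season`, `sm_anomaly_negative`,
#'   `retained` flags added.
#' @export
apply_filters <- function(monthly, monthly_temperature, monthly_sm_anomaly,
                          temp_threshold = 5, require_negative_pcor = FALSE) {
  if (!all(monthly$year_month %in% monthly_temperature$year_month) ||
      !all(monthly$year_month %in% monthly_sm_anomaly$year_month))
    stop("monthly axes are misaligned")
  out <- monthly |>
    dplyr::left_join(dplyr::select(monthly_temperature, "year_month",
                                   "temperature"), by = "year_month") |>
    dplyr::left_join(dplyr::select(monthly_sm_anomaly, "year_month",
                                   "sm_anomaly"), by = "year_month") |>
    dplyr::mutate(
      growing_season = is.finite(.data$temperature) &
        .data$temperature >= temp_threshold,
      sm_anomaly_negative = is.finite(.data$sm_anomaly) &
        .data$sm_anomaly < 0,
      retained = .data$eligible & .data$growing_season &
        .data$sm_anomaly_negative & is.finite(.data$pcor_monthly))
  if (require_negative_pcor)
    out$retained <- out$retained & out$pcor_monthly < 0
  out
}

#' Monthly SM-VPD coupling for every grid cell
#'
#' Runs the full coupling chain per cell: anomaly construction for soil
#' moisture and VPD, the lagged moving-window partial correlation, monthly
#' aggregation, and the growing-season / dry-anomaly / missing-data
#' filters.
#'
#' @param dataset an `smvpd_dataset` (or any list with a `daily` tibble
#'   holding `cell_id`, `date`, `sm`, `vpd`, `temperature`).
#' @inheritParams rolling_coupling
#' @inheritParams monthly_aggregate
#' @inheritParams apply_filters
#' @param frac LOWESS neighborhood fraction for detrending.
#' @return tibble of monthly coupling rows for all cells, with filter
#'   flags; attribute `params` records the settings.
#' @export
compute_coupling <- function(dataset, lag = 7L, window = 30L,
                             min_pairs = 24L, max_missing = 0.2,
                             temp_threshold = 5, frac = 0.4,
                             require_negative_pcor = FALSE) {
  daily <- dataset$daily
  out <- vector("list", length(unique(daily$cell_id)))
  ids <- unique(daily$cell_id)
  for (i in seq_along(ids)) {
    d <- daily[daily$cell_id == ids[i], ]
    out[[i]] <- cell_coupling(d, lag = lag, window = window,
                              min_pairs = min_pairs,
                              max_missing = max_missing,
                              temp_threshold = temp_threshold, frac = frac,
                              require_negative_pcor = require_negative_pcor)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "params") <- list(lag = lag, window = window,
                              min_pairs = min_pairs,
                              max_missing = max_missing,
                              temp_threshold = temp_threshold, frac = frac,
                              require_negative_pcor = require_negative_pcor)
  res
}

cell_coupling <- function(d, lag, window, min_pairs, max_missing,
                          temp_threshold, frac, require_negative_pcor) {
  sm_anom <- compute_anomalies(d$date, d$sm, frac = frac)
  vpd_anom <- compute_anomalies(d$date, d$vpd, frac = frac)
  daily_pc <- rolling_coupling(sm_anom, vpd_anom, d$date, lag = lag,
                               window = window, min_pairs = min_pairs)
  monthly <- monthly_aggregate(daily_pc, max_missing = max_missing)
  ymn <- year_month(d$date)
  m_temp <- tibble::tibble(year_month = ymn, temperature = d$temperature) |>
    dplyr::group_by(.data$year_month) |>
    dplyr::summarise(temperature = mean(.data$temperature, na.rm = TRUE),
                     .groups = "drop")
  m_sm <- tibble::tibble(year_month = ymn, sm_anomaly = as.numeric(sm_anom)) |>
    dplyr::group_by(.data$year_month) |>
    dplyr::summarise(sm_anomaly = mean(.data$sm_anomaly, na.rm = TRUE),
                     .groups = "drop")
  apply_filters(monthly, m_temp, m_sm, temp_threshold = temp_threshold,
                require_negative_pcor = require_negative_pcor) |>
    dplyr::mutate(cell_id = d$cell_id[1], .before = 1)
}
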
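#' Configuration for the synthetic coupled SM-VPD world
#'
#' Builds and validates the parameter set of the synthetic-data generator.
#' The generator emulates the statistical structure that the analysis
#' pipeline assumes: daily soil moisture with a seasonal cycle plus AR(1)
#' anomalies, daily VPD whose anomalies respond to lagged soil-moisture
#' anomalies with a cell- and time-varying coupling coefficient
#'
#'   beta(t) = b0 + b_lai * LAI(t) + b_phys * (Tr/LAI)(t)  (+ optional terms),
#'
#' and monthly predictor fields that are exact aggregates of the daily
#' fields.  `beta` carries the sign of the coupling itself: negative values
#' mean that a dry soil anomaly raises subsequent VPD (drought propagation),
#' so the default `b0`, `b_lai` and `b_phys` are all negative and increases
#' in leaf area or in canopy conductance strengthen the negative coupling.
#'
#' @param n_lat,n_lon grid extent; the product must be at least 9 so that a
#'   3 x 3 neighborhood exists for every interior cell.
#' @param start_date first simulated day.
#' @param n_years length of the record in whole years (minimum 3 so a
#'   monthly climatology is estimable).
#' @param seed integer seed; identical `(config, seed)` regenerates the
#'   dataset bit-for-bit.
#' @param lag_true lag (days) at which soil-moisture anomalies act on VPD.
#' @param b0 baseline coupling coefficient (kPa per unit SM anomaly).
#' @param b_lai coupling modulation per unit LAI (kPa per SM unit per m2/m2).
#' @param b_phys coupling modulation per unit normalized transpiration
#'   (kPa per SM unit per mm day-1 LAI-1).
#' @param b_extra optional named vector of coupling modulations applied to
#'   the standardized daily series of the remaining predictors
#'   (`precipitation`, `temperature`, `vpd`, `sm_surface`, `wind`); used to
#'   plant a dominant driver among the hydro-meteorological variables.
#' @param noise_sd_vpd standard deviation (kPa) of the white VPD noise.
#' @param sm_ar1 lag-1 autocorrelation of daily soil-moisture anomalies,
#'   in (0, 1).
#' @param sm_anom_sd stationary standard deviation of soil-moisture
#'   anomalies (m3/m3).
#' @param temp_coef kPa of VPD response per degree C of temperature anomaly.
#' @param cell_coef_sd relative spread of the per-cell coupling
#'   coefficients around `b0`, `b_lai`, `b_phys`.
#' @param climate_gradient list with elements `temperature` (range of
#'   long-term cell mean temperature, degrees C, mapped onto latitude rows)
#'   and `aridity` (range of the net-radiation/precipitation ratio, mapped
#'   onto longitude columns).
#' @param missing_rate fraction of daily values set missing at random
#'   (exercises the `< 20%` monthly aggregation rule); 0 disables.
#' @param cov_effect_bio,cov_effect_rzws prescribed loadings of the
#'   ancillary covariates (biodiversity, root-zone water storage) on the
#'   standardized per-cell physiological coupling coefficient; positive
#'   values plant a recoverable positive covariate-sensitivity link.
#'
#' @return an object of class `smvpd_config` (a validated list).
#' @export
synthetic_config <- function(n_lat = 15L, n_lon = 15L,
                             start_date = as.Date("2003-01-01"),
                             n_years = 12L, seed = 1L,
                             lag_true = 7L,
                             b0 = -0.5, b_lai = -3, b_phys = -5,
                             b_extra = NULL,
                             noise_sd_vpd = 0.3,
                             sm_ar1 = 0.9, sm_anom_sd = 0.03,
                             temp_coef = 0.05,
                             cell_coef_sd = 0.15,
                             climate_gradient = list(temperature = c(2, 28),
                                                     aridity = c(0.3, 3)),
                             missing_rate = 0,
                             cov_effect_bio = 1,
                             cov_effect_rzws = 1) {
  cfg <- list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
              start_date = as.Date(start_date), n_years = as.integer(n_years),
              seed = as.integer(seed), lag_true = as.integer(lag_true),
              b0 = b0, b_lai = b_lai, b_phys = b_phys,
              b_extra = b_extra, noise_sd_vpd = noise_sd_vpd,
              sm_ar1 = sm_ar1, sm_anom_sd = sm_anom_sd,
              temp_coef = temp_coef, cell_coef_sd = cell_coef_sd,
              climate_gradient = climate_gradient,
              missing_rate = missing_rate,
              cov_effect_bio = cov_effect_bio,
              cov_effect_rzws = cov_effect_rzws)
  num <- unlist(cfg[c("b0", "b_lai", "b_phys", "noise_sd_vpd", "sm_ar1",
                      "sm_anom_sd", "temp_coef", "cell_coef_sd",
                      "missing_rate", "cov_effect_bio", "cov_effect_rzws")])
  if (!all(is.finite(num))) stop("all numeric generator parameters must be finite")
  if (!is.null(cfg$b_extra)) {
    bad <- setdiff(names(cfg$b_extra), extra_predictors())
    if (length(bad) || !all(is.finite(cfg$b_extra)))
      stop("b_extra must be a finite named vector over: ",
           paste(extra_predictors(), collapse = ", "))
  }
  if (cfg$n_lat * cfg$n_lon < 9)
    stop("grid must contain at least 9 cells (3 x 3 pooling)")
  if (cfg$sm_ar1 <= 0 || cfg$sm_ar1 >= 1) stop("sm_ar1 must lie in (0, 1)")
  if (cfg$n_years < 3) stop("need n_years >= 3 to estimate a climatology")
  if (cfg$lag_true < 1) stop("lag_true must be a positive number of days")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(cfg, class = "smvpd_config")
}

extra_predictors <- function() {
  c("precipitation", "temperature", "vpd", "sm_surface", "wind")
}

#' Names of the candidate coupling drivers
#' @return character vector of the seven monthly predictor columns.
#' @export
predictor_names <- function() {
  c("lai", "transpiration_norm", extra_predictors())
}

# saturation vapor pressure (kPa) at temperature T (degrees C)
sat_vp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

ar1_series <- function(n, phi, innov_sd) {
  as.numeric(stats::filter(rnorm(n, sd = innov_sd), phi, method = "recursive"))
}

# centered running mean; edges padded with the nearest interior value
running_mean <- function(v, k) {
  out <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  first <- which(!is.na(out))[1]
  last <- max(which(!is.na(out)))
  out[seq_len(first - 1)] <- out[first]
  if (last < length(out)) out[(last + 1):length(out)] <- out[last]
  out
}

#' Generate a gridded synthetic dataset with known coupling truth
#'
#' Simulates daily soil moisture, VPD and temperature for every grid cell,
#' plus the seven monthly predictor fields, grid metadata (climate zones,
#' aridity, masks, ancillary covariates) and the per-cell generative truth.
#' Deterministic under `(config, seed)`.
#'
#' @param config an [synthetic_config()] object.
#' @param keep_daily_predictors keep the daily predictor fields in the
#'   result (needed only to audit monthly/daily consistency; roughly
#'   doubles memory).
#' @return a list of class `smvpd_dataset` with elements `daily`
#'   (tibble: `cell_id`, `date`, `sm`, `vpd`, `temperature`),
#'   `predictors_monthly`, `grid`, `truth` and `config`.
#' @export
generate_dataset <- function(config, keep_daily_predictors = FALSE) {
  stopifnot(inherits(config, "smvpd_config"))
  set.seed(config$seed)

  grid <- make_grid(config)
  truth <- make_truth(config, grid)

  end_date <- seq(config$start_date, by = paste(config$n_years, "years"),
                  length.out = 2)[2] - 1
  dates <- seq(config$start_date, end_date, by = "day")

  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cells[[i]] <- simulate_cell(config, grid[i, ], truth[i, ], dates,
                                keep_daily_predictors)
  }
  daily <- dplyr::bind_rows(lapply(cells, `[[`, "daily"))
  predictors <- dplyr::bind_rows(lapply(cells, `[[`, "monthly"))
  daily_predictors <- if (keep_daily_predictors)
    dplyr::bind_rows(lapply(cells, `[[`, "daily_predictors")) else NULL

  grid <- generate_ancillary(config, truth, grid)

  structure(list(daily = daily, predictors_monthly = predictors,
                 grid = grid, truth = truth, config = config,
                 daily_predictors = daily_predictors),
            class = "smvpd_dataset")
}

make_grid <- function(config) {
  tg <- config$climate_gradient$temperature
  ag <- config$climate_gradient$aridity
  nlat <- config$n_lat; nlon <- config$n_lon
  lat_idx <- rep(seq_len(nlat), each = nlon)
  lon_idx <- rep(seq_len(nlon), times = nlat)
  n <- nlat * nlon
  # warm at row 1, cold at row n_lat; wet at column 1, arid at column n_lon
  mean_temperature <- tg[2] - (tg[2] - tg[1]) * (lat_idx - 1) / max(1, nlat - 1) +
    rnorm(n, sd = 0.8)
  aridity <- exp(log(ag[1]) + (log(ag[2]) - log(ag[1])) *
                   (lon_idx - 1) / max(1, nlon - 1) + rnorm(n, sd = 0.08))
  vegetation_fraction <- pmin(95, pmax(6, 55 + 18 * rnorm(n) / (1 + 0.3 * aridity)))
  low_veg <- runif(n) < 0.03
  vegetation_fraction[low_veg] <- runif(sum(low_veg), 0, 5)
  irrigation_fraction <- runif(n, 0, 6)
  irrigated <- runif(n) < 0.03
  irrigation_fraction[irrigated] <- runif(sum(irrigated), 10, 40)

  zone <- ifelse(aridity >= 2, "arid",
                 ifelse(mean_temperature >= 18, "equatorial",
                        ifelse(mean_temperature >= 8, "temperate", "cold")))
  tibble::tibble(
    cell_id = sprintf("c%02d_%02d", lat_idx, lon_idx),
    lat_idx = lat_idx, lon_idx = lon_idx,
    lat = 60 - 50 * (lat_idx - 1) / max(1, nlat - 1),
    lon = 10 + 0.5 * (lon_idx - 1),
    climate_zone = zone,
    aridity = aridity,
    mean_temperature = mean_temperature,
    vegetation_fraction = vegetation_fraction,
    irrigation_fraction = irrigation_fraction,
    masked = vegetation_fraction <= 5 | irrigation_fraction >= 10)
}

make_truth <- function(config, grid) {
  n <- nrow(grid)
  jitter <- function(b) {
    m <- pmin(1.6, pmax(0.4, 1 + config$cell_coef_sd * rnorm(n)))
    b * m
  }
  tr <- tibble::tibble(
    cell_id = grid$cell_id,
    b0 = jitter(config$b0),
    b_lai = jitter(config$b_lai),
    b_phys = jitter(config$b_phys),
    noise_sd_vpd = config$noise_sd_vpd,
    sm_ar1 = config$sm_ar1,
    seed = config$seed)
  if (!is.null(config$b_extra)) {
    for (nm in names(config$b_extra))
      tr[[paste0("b_", nm)]] <- jitter(config$b_extra[[nm]])
  }
  tr
}

simulate_cell <- function(config, cell, truth, dates, keep_daily) {
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  s_summer <- cos(2 * pi * (doy - 196) / 365.25)  # +1 in mid July
  ar <- cell$aridity
  mt <- cell$mean_temperature

  # temperature: seasonal cycle + AR(1) synoptic anomalies
  t_clim <- mt + 10 * s_summer
  t_anom <- ar1_series(n, 0.8, 0.9)
  temperature <- t_clim + t_anom

  # soil moisture: wet-winter seasonal cycle + persistent AR(1) anomalies
  sm_base <- 0.10 + 0.18 / (1 + ar)
  sm_clim <- pmax(0.04, sm_base - 0.04 * s_summer)
  sm_anom <- ar1_series(n, config$sm_ar1,
                        config$sm_anom_sd * sqrt(1 - config$sm_ar1^2))
  sm <- pmax(0.005, sm_clim + sm_anom)

  # leaf area: climatological bell peaking in summer, slow anomalies
  lai_max <- pmax(0.4, 4.5 / (1 + 0.6 * ar)) * pmin(1, pmax(0.25, (mt + 5) / 25))
  seas <- pmin(1, pmax(0.2, (22 - mt) / 18))  # weak seasonality in warm cells
  g <- ((s_summer + 1) / 2)^(1 + 1.5 * seas)
  lai_clim <- lai_max * (0.25 + 0.75 * g)
  lai <- pmax(0.05, lai_clim + ar1_series(n, 0.98, 0.012 * lai_max))

  # conductance-like transpiration: Tr = g(t) * LAI * SM-stress *
  # VPD-response, so Tr/LAI (normalized transpiration) is independent of
  # LAI itself.  g(t) carries a slow lognormal AR(1) physiological state
  # (stomatal regulation beyond instantaneous SM/VPD), which gives the
  # physiology variable variance of its own, not collinear with structure
  # or weather.
  rh <- pmin(0.9, pmax(0.25, 0.35 + 0.4 / (1 + ar)))
  vpd_clim <- pmax(0.02, sat_vp(t_clim) * (1 - rh))
  stress <- pmin(1, pmax(0.05, (sm - 0.05) / 0.15))
  g_state <- exp(0.25 * ar1_series(n, 0.97, sqrt(1 - 0.97^2)))
  tr_norm <- 1.5 * g_state * stress * vpd_clim / (vpd_clim + 0.3)
  transpiration <- tr_norm * lai

  # extra daily fields (hydro-meteorological predictors)
  precipitation <- rbinom(n, 1, 0.35) *
    rgamma(n, shape = 0.8, rate = 0.8 * (0.5 + ar) / 2.5)
  wind <- pmax(0.2, 3 + ar1_series(n, 0.7, 0.7))
  sm_surface <- pmax(0.005, 0.75 * sm + rnorm(n, sd = 0.008))

  # coupling coefficient and VPD; beta is the signed coupling strength.
  # Hydro-meteorological modulations act on the 30-day running mean of the
  # daily field (standardized per cell): coupling responds to the slowly
  # varying state, which is what the monthly predictors can resolve.
  beta <- truth$b0 + truth$b_lai * lai + truth$b_phys * tr_norm
  if (!is.null(config$b_extra)) {
    extras <- list(precipitation = precipitation, temperature = temperature,
                   vpd = NULL, sm_surface = sm_surface, wind = wind)
    for (nm in names(config$b_extra)) {
      if (nm == "vpd") next  # vpd modulates through its own climatology below
      v <- running_mean(extras[[nm]], 31L)
      beta <- beta + truth[[paste0("b_", nm)]] * (v - mean(v)) / sd(v)
    }
  }
  lagged_sm_anom <- c(rep(0, config$lag_true), head(sm_anom, -config$lag_true))
  vpd <- vpd_clim + config$temp_coef * t_anom + beta * lagged_sm_anom +
    rnorm(n, sd = config$noise_sd_vpd)
  if (!is.null(config$b_extra) && "vpd" %in% names(config$b_extra)) {
    # vpd-driven modulation uses the deterministic climatology to stay causal
    zc <- (vpd_clim - mean(vpd_clim)) / sd(vpd_clim)
    vpd <- vpd + truth$b_vpd * zc * lagged_sm_anom
  }

  if (config$missing_rate > 0) {
    sm[runif(n) < config$missing_rate] <- NA_real_
    vpd[runif(n) < config$missing_rate] <- NA_real_
    temperature[runif(n) < config$missing_rate] <- NA_real_
  }

  daily <- tibble::tibble(cell_id = cell$cell_id, date = dates,
                          sm = sm, vpd = vpd, temperature = temperature)
  dp <- tibble::tibble(cell_id = cell$cell_id, date = dates,
                       lai = lai, transpiration = transpiration,
                       transpiration_norm = tr_norm,
                       precipitation = precipitation,
                       temperature = temperature, vpd = vpd,
                       sm_surface = sm_surface, wind = wind)
  monthly <- dp |>
    dplyr::mutate(year_month = year_month(.data$date)) |>
    dplyr::group_by(.data$cell_id, .data$year_month) |>
    dplyr::summarise(dplyr::across(c("lai", "transpiration",
                                     "transpiration_norm", "precipitation",
                                     "temperature", "vpd", "sm_surface",
                                     "wind"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  list(daily = daily, monthly = monthly,
       daily_predictors = if (keep_daily) dp else NULL)
}

#' Generate ancillary covariate fields tied to the coupling truth
#'
#' Fills the `biodiversity` and `rootzone_storage` columns of the grid
#' metadata with fields that have a prescribed monotone relationship to the
#' cells' true physiological coupling coefficient (standardized `b_phys`),
#' plus temperature and aridity confounding and independent noise.  With the
#' default positive loadings, cells whose coupling is more strongly
#' modulated by canopy conductance (less negative `b_phys`) carry higher
#' biodiversity and root-zone storage, so the binned partial-correlation
#' stage has a recoverable positive signal; loadings of 0 give a null world.
#'
#' @param config an [synthetic_config()] object.
#' @param truth per-cell truth table from [generate_dataset()].
#' @param grid grid metadata (built internally when omitted).
#' @return the grid tibble with `biodiversity` and `rootzone_storage` added.
#' @export
generate_ancillary <- function(config, truth, grid = NULL) {
  stopifnot(inherits(config, "smvpd_config"))
  if (is.null(grid)) {
    set.seed(config$seed)
    grid <- make_grid(config)
  }
  set.seed(config$seed + 99991L)
  n <- nrow(grid)
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, n)
  z_phys <- zs(truth$b_phys)
  z_t <- zs(grid$mean_temperature)
  z_a <- zs(grid$aridity)
  grid$biodiversity <- pmax(
    1, 400 + 180 * config$cov_effect_bio * z_phys +
      120 * z_t - 80 * z_a + rnorm(n, sd = 60))
  grid$rootzone_storage <- pmax(
    5, 180 + 70 * config$cov_effect_rzws * z_phys -
      40 * z_a + 25 * z_t + rnorm(n, sd = 30))
  grid
}
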
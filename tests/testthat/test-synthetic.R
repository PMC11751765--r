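test_that("config validation rejects invalid worlds", {
  expect_error(synthetic_config(n_lat = 2, n_lon = 2), "9 cells")
  expect_error(synthetic_config(sm_ar1 = 1), "sm_ar1")
  expect_error(synthetic_config(sm_ar1 = 0), "sm_ar1")
  expect_error(synthetic_config(n_years = 2), "n_years")
  expect_error(synthetic_config(b0 = Inf), "finite")
  expect_error(synthetic_config(b_extra = c(nonsense = 1)), "b_extra")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_s3_class(synthetic_config(), "smvpd_config")
})

test_that("regeneration with the same config is identical field by field", {
  cfg <- tiny_config(seed = 99L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$daily, d2$daily)
  expect_identical(d1$predictors_monthly, d2$predictors_monthly)
  expect_identical(d1$grid, d2$grid)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(tiny_config(seed = 100L))
  expect_false(identical(d1$daily, d3$daily))
})

test_that("grid metadata honors the mask and aridity invariants", {
  cfg <- synthetic_config(n_lat = 12, n_lon = 12, n_years = 3, seed = 4)
  g <- generate_dataset(cfg)$grid
  expect_equal(g$masked,
               g$vegetation_fraction <= 5 | g$irrigation_fraction >= 10)
  expect_true(all(g$aridity > 0))
  expect_true(all(c("biodiversity", "rootzone_storage") %in% names(g)))
  expect_true(all(g$biodiversity > 0) && all(g$rootzone_storage > 0))
})

test_that("soil-moisture anomaly autocorrelation matches the configured AR(1)", {
  cfg <- tiny_config(n_years = 10L, seed = 8L, sm_ar1 = 0.85)
  ds <- generate_dataset(cfg)
  for (id in unique(ds$daily$cell_id)[1:3]) {
    d <- ds$daily[ds$daily$cell_id == id, ]
    a <- as.numeric(compute_anomalies(d$date, d$sm))
    r1 <- cor(a[-1], a[-length(a)])
    expect_lt(abs(r1 - 0.85), 0.05)
  }
})

test_that("monthly predictors are exact aggregates of the daily fields", {
  cfg <- tiny_config(seed = 13L)
  ds <- generate_dataset(cfg, keep_daily_predictors = TRUE)
  agg <- ds$daily_predictors |>
    dplyr::mutate(year_month = year_month(date)) |>
    dplyr::group_by(cell_id, year_month) |>
    dplyr::summarise(lai = mean(lai),
                     transpiration_norm = mean(transpiration_norm),
                     wind = mean(wind), .groups = "drop")
  j <- dplyr::inner_join(agg, ds$predictors_monthly,
                         by = c("cell_id", "year_month"),
                         suffix = c("", ".pm"))
  expect_equal(j$lai, j$lai.pm, tolerance = 1e-12)
  expect_equal(j$transpiration_norm, j$transpiration_norm.pm,
               tolerance = 1e-12)
  expect_equal(j$wind, j$wind.pm, tolerance = 1e-12)
  expect_true(all(ds$daily_predictors$lai >= 0))
  expect_true(all(ds$daily_predictors$transpiration[
    ds$daily_predictors$lai > 0] > 0))
})

test_that("zero-effect worlds have near-zero mean coupling", {
  cfg <- tiny_config(n_years = 8L, seed = 17L, b0 = 0, b_lai = 0,
                     b_phys = 0)
  ds <- generate_dataset(cfg)
  cp <- compute_coupling(ds)
  expect_lt(abs(mean(cp$pcor_monthly[cp$eligible], na.rm = TRUE)), 0.05)
})

test_that("the noise-free limit yields negative coupling in every window", {
  cfg <- tiny_config(n_years = 5L, seed = 19L, b0 = -5, b_lai = 0,
                     b_phys = 0, noise_sd_vpd = 1e-6, temp_coef = 0)
  ds <- generate_dataset(cfg)
  d <- ds$daily[ds$daily$cell_id == ds$grid$cell_id[5], ]
  sm_a <- compute_anomalies(d$date, d$sm)
  vpd_a <- compute_anomalies(d$date, d$vpd)
  rc <- rolling_coupling(sm_a, vpd_a, d$date)
  # anomalies are estimated, so the limit is approximate: uniformly
  # negative, and near -1 in most windows
  expect_true(all(rc$pcor[is.finite(rc$pcor)] < 0))
  expect_lt(stats::quantile(rc$pcor, 0.9, na.rm = TRUE), -0.6)
  expect_lt(median(rc$pcor, na.rm = TRUE), -0.8)
})

test_that("missing-value injection respects the configured rate", {
  cfg <- tiny_config(n_years = 4L, seed = 23L, missing_rate = 0.1)
  ds <- generate_dataset(cfg)
  expect_lt(abs(mean(is.na(ds$daily$sm)) - 0.1), 0.02)
  expect_lt(abs(mean(is.na(ds$daily$vpd)) - 0.1), 0.02)
  # the monthly missing-data rule now drops some months
  cp <- compute_coupling(ds)
  expect_gt(sum(!cp$eligible), 0)
})

test_that("LAI and normalized transpiration are only moderately collinear", {
  cfg <- synthetic_config(n_lat = 4, n_lon = 4, n_years = 10, seed = 29)
  ds <- generate_dataset(cfg)
  pm <- ds$predictors_monthly[ds$predictors_monthly$temperature >= 5, ]
  r <- vapply(split(pm, pm$cell_id), function(d)
    cor(d$lai, d$transpiration_norm), numeric(1))
  expect_lt(abs(median(r)), 0.5)
})

test_that("ancillary covariates carry the prescribed monotone link to b_phys", {
  cfg <- synthetic_config(n_lat = 10, n_lon = 10, n_years = 3, seed = 31,
                          cov_effect_bio = 1, cov_effect_rzws = 1)
  ds <- generate_dataset(cfg)
  j <- dplyr::inner_join(ds$grid, ds$truth, by = "cell_id")
  ps <- partial_spearman(j$biodiversity, j$b_phys,
                         j[, c("aridity", "mean_temperature")])
  expect_gt(ps$rho, 0.3)
  # zero prescribed effect: association disappears
  cfg0 <- synthetic_config(n_lat = 10, n_lon = 10, n_years = 3, seed = 31,
                           cov_effect_bio = 0, cov_effect_rzws = 0)
  ds0 <- generate_dataset(cfg0)
  j0 <- dplyr::inner_join(ds0$grid, ds0$truth, by = "cell_id")
  ps0 <- partial_spearman(j0$biodiversity, j0$b_phys,
                          j0[, c("aridity", "mean_temperature")])
  expect_lt(abs(ps0$rho), 0.25)
})
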
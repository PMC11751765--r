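make_table <- function(n, p, f, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  tab <- as.data.frame(X)
  tab$pcor_monthly <- f(X) + rnorm(n, sd = noise_sd)
  tab
}

test_that("the forest learns a smooth monotone signal and refuses pure noise", {
  tab <- make_table(200, 3, function(X) tanh(X[, 1]), noise_sd = 0.1)
  m <- fit_cell_model(tab, paste0("x", 1:3))
  expect_gt(m$oob_r2, 0.8)

  r2 <- vapply(1:50, function(s) {
    tab <- make_table(120, 5, function(X) 0, noise_sd = 1, seed = 100 + s)
    fit_cell_model(tab, paste0("x", 1:5))$oob_r2
  }, numeric(1))
  expect_lte(mean(r2), 0.05)
})

test_that("fits are deterministic under the fixed random state", {
  tab <- make_table(120, 4, function(X) X[, 1] - X[, 2])
  m1 <- fit_cell_model(tab, paste0("x", 1:4), seed = 42)
  m2 <- fit_cell_model(tab, paste0("x", 1:4), seed = 42)
  expect_identical(m1$oob_r2, m2$oob_r2)
  expect_identical(predict(m1, tab), predict(m2, tab))
  m3 <- fit_cell_model(tab, paste0("x", 1:4), seed = 43)
  expect_false(identical(m1$oob_r2, m3$oob_r2))
})

test_that("a constant target yields undefined out-of-bag skill", {
  tab <- make_table(50, 3, function(X) 0, noise_sd = 0)
  tab$pcor_monthly <- 0.5
  m <- fit_cell_model(tab, paste0("x", 1:3))
  expect_true(is.na(m$oob_r2))
})

test_that("SHAP contributions are additive and concentrate on the live feature", {
  tab <- make_table(150, 2, function(X) sin(X[, 1]), noise_sd = 0)
  m <- fit_cell_model(tab, c("x1", "x2"))
  sh <- shap_decompose(m, tab)
  pred <- predict(m, tab)
  expect_lt(max(abs(attr(sh, "base") + rowSums(sh) - pred)), 1e-6)
  expect_gt(mean(abs(sh[, "x1"])), 5 * mean(abs(sh[, "x2"])))
})

test_that("TreeSHAP equals brute-force Shapley enumeration on a small tree", {
  tab <- make_table(40, 3, function(X) X[, 1] + 0.5 * X[, 2] * X[, 3],
                    noise_sd = 0.05, seed = 77)
  m <- fit_cell_model(tab, paste0("x", 1:3), ntree = 1, max_features = 1,
                      min_leaf = 3, seed = 5)
  tr <- m$trees[[1]]
  # path-dependent conditional expectation of the tree given feature set S
  expv <- function(x, S) {
    rec <- function(node) {
      f <- tr$feature[node + 1]
      if (f < 0) return(tr$value[node + 1])
      if ((f + 1) %in% S) {
        if (x[f + 1] <= tr$threshold[node + 1]) rec(tr$left[node + 1])
        else rec(tr$right[node + 1])
      } else {
        wl <- tr$cover[tr$left[node + 1] + 1]
        wr <- tr$cover[tr$right[node + 1] + 1]
        (wl * rec(tr$left[node + 1]) + wr * rec(tr$right[node + 1])) /
          (wl + wr)
      }
    }
    rec(0)
  }
  brute <- function(x) {
    phi <- numeric(3)
    for (j in 1:3) {
      others <- setdiff(1:3, j)
      for (k in 0:2) {
        combs <- if (k == 0) list(integer(0)) else
          asplit(utils::combn(others, k), 2)
        for (S in combs) {
          w <- factorial(k) * factorial(3 - k - 1) / factorial(3)
          phi[j] <- phi[j] + w * (expv(x, c(S, j)) - expv(x, S))
        }
      }
    }
    phi
  }
  sh <- shap_decompose(m, tab)
  X <- as.matrix(tab[, 1:3])
  err <- vapply(1:15, function(i) max(abs(brute(X[i, ]) - sh[i, ])),
                numeric(1))
  expect_lt(max(err), 1e-10)
})

test_that("importance ranks order by mean absolute SHAP with name tie-breaks", {
  sh <- cbind(a = c(0.3, -0.3, 0.3), b = c(0.1, -0.1, 0.1),
              c = c(0, 0, 0))
  r <- rank_importance(sh)
  expect_equal(r$importance_rank[r$predictor == "a"], 1L)
  expect_equal(r$importance_rank[r$predictor == "b"], 2L)
  expect_equal(r$importance_rank[r$predictor == "c"], 3L)
  expect_setequal(r$importance_rank, 1:3)
  # exact tie broken alphabetically
  sh2 <- cbind(zed = c(0.2, -0.2), alf = c(-0.2, 0.2))
  r2 <- rank_importance(sh2)
  expect_equal(r2$importance_rank[r2$predictor == "alf"], 1L)
})

test_that("Theil-Sen slope is exact on lines and equals brute-force enumeration", {
  x <- seq(-3, 3, length.out = 25)
  ts <- theil_sen(x, 2 * x + 1)
  expect_equal(ts$slope, 2, tolerance = 1e-14)
  expect_equal(ts$intercept, 1, tolerance = 1e-12)

  const <- theil_sen(x, rep(4, 25))
  expect_equal(const$slope, 0)
  expect_false(const$significant)

  set.seed(12)
  y <- 0.5 * x + rnorm(25, sd = 0.3)
  y[10] <- 50  # gross outlier
  ts2 <- theil_sen(x, y)
  expect_identical(ts2$slope, theil_sen_bruteforce(x, y))

  degen <- theil_sen(rep(1, 10), rnorm(10))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$slope))
})

test_that("training tables pool the 3 x 3 neighborhood", {
  grid <- tibble::tibble(
    cell_id = sprintf("c%02d_%02d", rep(1:3, each = 3), rep(1:3, 3)),
    lat_idx = rep(1:3, each = 3), lon_idx = rep(1:3, 3), masked = FALSE)
  ym <- seq(as.Date("2003-05-01"), by = "month", length.out = 12)
  coupling <- tidyr::expand_grid(cell_id = grid$cell_id, year_month = ym) |>
    dplyr::mutate(pcor_monthly = -0.3, retained = TRUE)
  predictors <- tidyr::expand_grid(cell_id = grid$cell_id, year_month = ym) |>
    dplyr::mutate(lai = 1, transpiration_norm = 0.5)
  tab <- assemble_training_table("c02_02", coupling, predictors, grid,
                                 features = c("lai", "transpiration_norm"))
  expect_equal(nrow(tab), 108)  # interior: 9 cells x 12 months
  tab_corner <- assemble_training_table("c01_01", coupling, predictors, grid,
                                        features = c("lai",
                                                     "transpiration_norm"))
  expect_equal(nrow(tab_corner), 48)  # corner: 4 cells x 12 months
  grid$masked[grid$cell_id == "c03_03"] <- TRUE
  expect_error(assemble_training_table("c03_03", coupling, predictors, grid),
               "masked")
})

test_that("the sample-size screen excludes 19 pooled rows but keeps 20", {
  grid <- tibble::tibble(cell_id = c("a", "b"), lat_idx = c(1, 1),
                         lon_idx = c(1, 2), masked = FALSE)
  ym <- seq(as.Date("2003-05-01"), by = "month", length.out = 10)
  mk <- function(n_months) {
    coupling <- tidyr::expand_grid(cell_id = c("a", "b"),
                                   year_month = ym[seq_len(n_months)]) |>
      dplyr::mutate(pcor_monthly = rnorm(dplyr::n(), -0.3, 0.1),
                    retained = TRUE)
    predictors <- tidyr::expand_grid(cell_id = c("a", "b"),
                                     year_month = ym[seq_len(n_months)]) |>
      dplyr::mutate(lai = rnorm(dplyr::n(), 2),
                    transpiration_norm = rnorm(dplyr::n(), 0.5))
    attribution_sweep(coupling, predictors, grid,
                      features = c("lai", "transpiration_norm"))
  }
  set.seed(3)
  at20 <- mk(10)  # 2 cells x 10 months = 20 rows
  expect_true(all(at20$cells$n_samples == 20))
  expect_true(all(is.finite(at20$cells$oob_r2)))
  at19 <- mk(9)   # 18 rows < 20
  expect_true(all(!at19$cells$passed_screen))
  expect_true(all(is.na(at19$cells$oob_r2)))
})

test_that("the attribution sweep is deterministic", {
  cfg <- tiny_config(n_years = 6L, seed = 14L)
  ds <- generate_dataset(cfg)
  cp <- compute_coupling(ds)
  a1 <- attribution_sweep(cp, ds$predictors_monthly, ds$grid)
  a2 <- attribution_sweep(cp, ds$predictors_monthly, ds$grid)
  expect_identical(a1$cells, a2$cells)
  expect_identical(a1$drivers, a2$drivers)
})

test_that("slope signs are robust to dropping the collinear vegetation partner", {
  cfg <- synthetic_config(n_lat = 4, n_lon = 4, n_years = 10, seed = 33)
  ds <- generate_dataset(cfg)
  cp <- compute_coupling(ds)
  full <- attribution_sweep(cp, ds$predictors_monthly, ds$grid)
  red <- attribution_sweep(cp, ds$predictors_monthly, ds$grid,
                           drop_predictors = "transpiration_norm")
  lai_full <- full$drivers[full$drivers$predictor == "lai", ]
  lai_red <- red$drivers[red$drivers$predictor == "lai", ]
  j <- dplyr::inner_join(lai_full, lai_red, by = "cell_id",
                         suffix = c("_full", "_red"))
  j <- j[j$significant_full, ]
  expect_gt(nrow(j), 2)
  flipped <- sign(j$theil_sen_slope_full) != sign(j$theil_sen_slope_red)
  expect_lt(mean(flipped), 0.1)
})
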
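#' Pooled 3 x 3 training table for one grid cell
#'
#' Collects the retained monthly coupling rows of the focal cell and of its
#' up-to-8 existing grid neighbors (no wraparound at edges) and joins the
#' monthly predictor values, so the cell model trains on a spatially
#' homogeneous neighborhood.  Cells pooling fewer than `min_samples` rows
#' are excluded downstream ("fewer than 20" excludes 19, not 20).
#'
#' @param cell_id focal cell identifier.
#' @param coupling monthly coupling tibble from [compute_coupling()].
#' @param predictors monthly predictor tibble (`cell_id`, `year_month`,
#'   predictor columns with absolute values).
#' @param grid grid metadata with `cell_id`, `lat_idx`, `lon_idx`, `masked`.
#' @param features predictor columns to keep.
#' @return tibble of training rows (target `pcor_monthly` plus features).
#' @export
assemble_training_table <- function(cell_id, coupling, predictors, grid,
                                    features = predictor_names()) {
  g <- grid[grid$cell_id == cell_id, ]
  if (nrow(g) != 1) stop("unknown cell_id: ", cell_id)
  if (isTRUE(g$masked)) stop("cell ", cell_id, " is masked")
  nb <- grid[abs(grid$lat_idx - g$lat_idx) <= 1 &
               abs(grid$lon_idx - g$lon_idx) <= 1, ]
  rows <- coupling[coupling$cell_id %in% nb$cell_id & coupling$retained, ,
                   drop = FALSE]
  out <- dplyr::inner_join(
    dplyr::select(rows, "cell_id", "year_month", "pcor_monthly"),
    dplyr::select(predictors, "cell_id", "year_month",
                  dplyr::all_of(features)),
    by = c("cell_id", "year_month"))
  out[complete.cases(out), , drop = FALSE]
}

#' Rank driver importance from SHAP contributions
#'
#' Importance of a predictor is the mean of the absolute SHAP
#' contributions over all rows; rank 1 is the most important.  Ranks are
#' comparable only within one cell's model.  Exact ties are broken by
#' predictor name (alphabetical).
#'
#' @param shap matrix from [shap_decompose()] (columns = predictors).
#' @return tibble with `predictor`, `mean_abs_shap`, `importance_rank`.
#' @export
rank_importance <- function(shap) {
  imp <- colMeans(abs(shap))
  ord <- order(-imp, names(imp))
  tibble::tibble(predictor = names(imp),
                 mean_abs_shap = as.numeric(imp),
                 importance_rank = match(names(imp), names(imp)[ord]))
}

#' Theil-Sen sensitivity slope with a Kendall-tau significance test
#'
#' The slope is the median of all pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)` over pairs with distinct `x`; applied to a
#' predictor's SHAP contributions against the predictor's values it
#' measures the sensitivity of the coupling to that driver, robustly to
#' outliers.  The two-sided p-value comes from the Kendall-tau test of
#' monotone association between `x` and `y` (normal approximation, tie
#' corrected).
#'
#' @param x predictor values.
#' @param y SHAP contributions (or any response).
#' @param alpha significance level for the `significant` flag.
#' @return list with `slope`, `intercept`, `p`, `significant`, `n`,
#'   `degenerate`.
#' @export
theil_sen <- function(x, y, alpha = 0.01) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2)
    return(list(slope = NA_real_, intercept = NA_real_, p = NA_real_,
                significant = FALSE, n = n, degenerate = TRUE))
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slope <- median(dy[keep] / dx[keep])
  intercept <- median(y - slope * x)
  p <- if (sd(y) == 0) 1 else
    suppressWarnings(cor.test(x, y, method = "kendall",
                              exact = FALSE)$p.value)
  list(slope = slope, intercept = intercept, p = p,
       significant = is.finite(p) && p < alpha, n = n, degenerate = FALSE)
}

#' Driver attribution for every grid cell
#'
#' For each unmasked cell: pool the 3 x 3 training table, apply the sample
#' screen (`n >= min_samples`), fit the random forest, apply the skill
#' screen (`oob_r2 >= oob_threshold`), decompose predictions with exact
#' TreeSHAP, rank driver importance by mean absolute contribution, and
#' estimate the Theil-Sen sensitivity of each driver's SHAP values to the
#' driver itself with its Kendall-tau p-value.  Per-cell failures are
#' collected in a report; the sweep never aborts on a single cell.
#'
#' @inheritParams assemble_training_table
#' @param min_samples minimum pooled rows per cell.
#' @param oob_threshold minimum out-of-bag R-squared.
#' @param alpha two-sided significance level for sensitivity slopes.
#' @inheritParams fit_cell_model
#' @param drop_predictors optional predictors to exclude (collinearity
#'   robustness check).
#' @return object of class `smvpd_attribution`: list with `cells`
#'   (per-cell skill/screen table), `drivers` (per cell x predictor
#'   importance, rank, slope, p, significance) and `report`.
#' @export
attribution_sweep <- function(coupling, predictors, grid,
                              features = predictor_names(),
                              min_samples = 20L, oob_threshold = 0.2,
                              alpha = 0.01, ntree = 100L,
                              max_features = 0.3, min_leaf = 5L,
                              seed = 42L, drop_predictors = NULL) {
  features <- setdiff(features, drop_predictors)
  ids <- grid$cell_id[!grid$masked]
  cells <- vector("list", length(ids))
  drivers <- vector("list", length(ids))
  failures <- character()
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- tryCatch(
      attribute_cell(id, coupling, predictors, grid, features,
                     min_samples, oob_threshold, alpha, ntree,
                     max_features, min_leaf, seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(id, ": ", conditionMessage(res)))
      cells[[i]] <- tibble::tibble(cell_id = id, n_samples = NA_integer_,
                                   oob_r2 = NA_real_, passed_screen = FALSE)
    } else {
      cells[[i]] <- res$cell
      drivers[[i]] <- res$drivers
    }
  }
  cells <- dplyr::bind_rows(cells)
  structure(list(cells = cells,
                 drivers = dplyr::bind_rows(drivers),
                 report = list(n_cells = length(ids),
                               n_passed = sum(cells$passed_screen),
                               failures = failures,
                               features = features,
                               params = list(min_samples = min_samples,
                                             oob_threshold = oob_threshold,
                                             alpha = alpha, ntree = ntree,
                                             max_features = max_features,
                                             min_leaf = min_leaf,
                                             seed = seed))),
            class = "smvpd_attribution")
}

attribute_cell <- function(id, coupling, predictors, grid, features,
                           min_samples, oob_threshold, alpha, ntree,
                           max_features, min_leaf, seed) {
  table <- assemble_training_table(id, coupling, predictors, grid, features)
  n <- nrow(table)
  if (n < min_samples)
    return(list(cell = tibble::tibble(cell_id = id, n_samples = n,
                                      oob_r2 = NA_real_,
                                      passed_screen = FALSE),
                drivers = NULL))
  model <- fit_cell_model(table, features, ntree = ntree,
                          max_features = max_features, min_leaf = min_leaf,
                          seed = seed)
  passed <- is.finite(model$oob_r2) && model$oob_r2 >= oob_threshold
  cell <- tibble::tibble(cell_id = id, n_samples = n, oob_r2 = model$oob_r2,
                         passed_screen = passed)
  if (!passed) return(list(cell = cell, drivers = NULL))

  shap <- shap_decompose(model, table)
  ranks <- rank_importance(shap)
  sens <- lapply(features, function(f) {
    ts <- theil_sen(table[[f]], shap[, f], alpha = alpha)
    tibble::tibble(predictor = f, theil_sen_slope = ts$slope,
                   slope_p = ts$p, significant = ts$significant,
                   degenerate = ts$degenerate)
  })
  drivers <- dplyr::left_join(ranks, dplyr::bind_rows(sens),
                              by = "predictor")
  drivers <- dplyr::mutate(drivers, cell_id = id, .before = 1)
  list(cell = cell, drivers = drivers)
}

#' @export
print.smvpd_attribution <- function(x, ...) {
  cat(sprintf("<smvpd_attribution> %d cells, %d passed screens\n",
              x$report$n_cells, x$report$n_passed))
  invisible(x)
}
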
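#' Aridity index: net radiation over precipitation
#'
#' Net radiation expressed in mm water equivalent divided by precipitation
#' (mm); values above 1 indicate an energy surplus (dry climate).
#' Non-positive precipitation yields `NA` with a flag.
#'
#' @param net_radiation_mm net radiation, mm water equivalent.
#' @param precipitation_mm precipitation, mm.
#' @return tibble with `aridity` and logical `flagged`.
#' @export
aridity_index <- function(net_radiation_mm, precipitation_mm) {
  bad <- !is.finite(precipitation_mm) | precipitation_mm <= 0
  out <- ifelse(bad, NA_real_, net_radiation_mm / precipitation_mm)
  tibble::tibble(aridity = out, flagged = bad)
}

#' Median sensitivity per climate zone
#'
#' @param values per-cell sensitivities.
#' @param zones climate-zone label per cell.
#' @return tibble with `zone`, `median_sensitivity`, `n_cells` (zones with
#'   no finite value omitted).
#' @export
zone_median <- function(values, zones) {
  d <- tibble::tibble(zone = zones, value = values) |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(median_sensitivity = median(.data$value),
                     n_cells = dplyr::n(), .groups = "drop")
  d
}

bin_labels <- function(x, edges) {
  cut(x, breaks = edges, right = FALSE, include.lowest = FALSE)
}

#' Default aridity and temperature bin edges
#' @name bin_edges
#' @return numeric vector of bin edges.
#' @export
default_aridity_edges <- function() c(0, 0.5, 0.8, 1.2, 2, 5, Inf)

#' @rdname bin_edges
#' @export
default_temperature_edges <- function() seq(-10, 35, by = 5)

#' Mean sensitivity over aridity x temperature bins
#'
#' Cells are partitioned into `[low, high)` aridity and temperature bins;
#' each bin reports the mean and median sensitivity over its cells with a
#' significant slope, and is suppressed (statistics withheld) when fewer
#' than `min_cells` significant cells fall in it.
#'
#' @param sensitivity per-cell sensitivity values.
#' @param significant logical flag per cell.
#' @param aridity,temperature per-cell covariates.
#' @param aridity_edges,temp_edges strictly increasing bin edges.
#' @param min_cells minimum significant cells for a bin to be reported.
#' @return tibble of bin summaries; attribute `n_unbinned` counts cells
#'   outside every bin.
#' @export
bin_means <- function(sensitivity, significant, aridity, temperature,
                      aridity_edges = default_aridity_edges(),
                      temp_edges = default_temperature_edges(),
                      min_cells = 10L) {
  if (is.unsorted(aridity_edges, strictly = TRUE) ||
      is.unsorted(temp_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  ab <- bin_labels(aridity, aridity_edges)
  tb <- bin_labels(temperature, temp_edges)
  ok <- is.finite(sensitivity)
  d <- tibble::tibble(sensitivity, significant = significant & ok,
                      aridity_bin = ab, temperature_bin = tb)[ok, ]
  n_unbinned <- sum(is.na(d$aridity_bin) | is.na(d$temperature_bin))
  d <- d[!is.na(d$aridity_bin) & !is.na(d$temperature_bin), ]
  out <- d |>
    dplyr::group_by(.data$aridity_bin, .data$temperature_bin) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_significant_cells = sum(.data$significant),
      mean_sensitivity = if (any(.data$significant))
        mean(.data$sensitivity[.data$significant]) else NA_real_,
      median_sensitivity = if (any(.data$significant))
        median(.data$sensitivity[.data$significant]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(suppressed = .data$n_significant_cells < min_cells)
  out$mean_sensitivity[out$suppressed] <- NA_real_
  out$median_sensitivity[out$suppressed] <- NA_real_
  attr(out, "n_unbinned") <- n_unbinned
  out
}

#' Partial Spearman correlation controlling for covariates
#'
#' All series are rank-transformed (ties averaged); the statistic is the
#' partial Pearson correlation of the ranked `x` and `y` given the ranked
#' controls, with a two-sided t-test p-value on `n - 2 - k` degrees of
#' freedom.  Constant controls are dropped (reducing to the ordinary
#' Spearman correlation when all controls are constant); constant `x` or
#' `y` is degenerate.
#'
#' @param x covariate values.
#' @param y sensitivity values.
#' @param controls data frame or matrix of control variables.
#' @return list with `rho`, `p`, `n`, `degenerate`.
#' @export
partial_spearman <- function(x, y, controls) {
  controls <- as.data.frame(controls)
  ok <- complete.cases(x, y, controls)
  x <- x[ok]; y <- y[ok]
  controls <- controls[ok, , drop = FALSE]
  n <- length(x)
  if (n < 4 || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  keep <- vapply(controls, function(v) sd(v) > 0, logical(1))
  controls <- controls[, keep, drop = FALSE]
  k <- ncol(controls)
  rx <- rank(x); ry <- rank(y)
  if (k == 0) {
    rho <- cor(rx, ry)
  } else {
    rz <- vapply(controls, rank, numeric(n))
    cm <- cor(cbind(rx, ry, rz))
    om <- tryCatch(solve(cm), error = function(e) NULL)
    if (!is.null(om)) {
      rho <- -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
    } else {
      # singular rank-correlation matrix (e.g. perfectly concordant x, y):
      # fall back to the residual form of the partial correlation
      ex <- resid(lm(rx ~ rz))
      ey <- resid(lm(ry ~ rz))
      if (sd(ex) == 0 || sd(ey) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
      rho <- cor(ex, ey)
    }
  }
  rho <- max(-1, min(1, rho))
  df <- n - 2 - k
  if (df < 1 || abs(rho) == 1) {
    p <- if (abs(rho) == 1) 0 else NA_real_
  } else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure: sorted p-values are compared with
#' `i * q / m`; adjusted p-values are monotone after sorting and rejections
#' are `p_adjusted <= q`.  `NA` p-values are carried through unflagged.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate.
#' @return tibble with `p_raw`, `p_adjusted`, `significant`.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  finite <- p[is.finite(p)]
  if (length(finite) && (any(finite < 0) || any(finite > 1)))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p_raw = p, p_adjusted = adj,
                 significant = !is.na(adj) & adj <= q)
}

#' Binned covariate analysis of coupling sensitivities
#'
#' Within every aridity x temperature bin, the partial Spearman correlation
#' between a covariate (biodiversity or root-zone water storage) and the
#' per-cell sensitivity is computed, controlling for aridity and
#' temperature.  Bins with fewer than `min_cells` usable cells are
#' disregarded.  Raw significance is tested at `alpha`; the
#' Benjamini-Hochberg adjustment runs jointly across all bins and both
#' covariates for a given sensitivity type, giving the second
#' ("BH-robust") flag.
#'
#' @param cells tibble with one row per cell: `sensitivity`, covariate
#'   columns, `aridity`, `temperature`.
#' @param covariates names of the covariate columns to test.
#' @inheritParams bin_means
#' @param min_cells minimum cells per bin.
#' @param alpha raw two-sided significance level.
#' @param q false-discovery rate for the BH adjustment.
#' @return tibble of bin x covariate results with `partial_rho`, `p_raw`,
#'   `p_adjusted`, `significant_raw`, `significant_bh`, `suppressed`,
#'   `degenerate`.
#' @export
covariate_analysis <- function(cells,
                               covariates = c("biodiversity",
                                              "rootzone_storage"),
                               aridity_edges = default_aridity_edges(),
                               temp_edges = default_temperature_edges(),
                               min_cells = 20L, alpha = 0.05, q = 0.05) {
  stopifnot(all(c("sensitivity", "aridity", "temperature", covariates)
                %in% names(cells)))
  cells <- cells[is.finite(cells$sensitivity), , drop = FALSE]
  cells$aridity_bin <- bin_labels(cells$aridity, aridity_edges)
  cells$temperature_bin <- bin_labels(cells$temperature, temp_edges)
  cells <- cells[!is.na(cells$aridity_bin) & !is.na(cells$temperature_bin), ]
  combos <- unique(cells[, c("aridity_bin", "temperature_bin")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- cells[cells$aridity_bin == combos$aridity_bin[i] &
                   cells$temperature_bin == combos$temperature_bin[i], ]
    for (cv in covariates) {
      suppressed <- nrow(sub) < min_cells
      if (suppressed) {
        res <- list(rho = NA_real_, p = NA_real_, n = nrow(sub),
                    degenerate = FALSE)
      } else {
        res <- partial_spearman(sub[[cv]], sub$sensitivity,
                                sub[, c("aridity", "temperature")])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        aridity_bin = combos$aridity_bin[i],
        temperature_bin = combos$temperature_bin[i],
        covariate = cv, n_cells = nrow(sub),
        partial_rho = res$rho, p_raw = res$p,
        suppressed = suppressed, degenerate = res$degenerate)
    }
  }
  out <- dplyr::bind_rows(rows)
  bh <- benjamini_hochberg(out$p_raw, q = q)
  out$p_adjusted <- bh$p_adjusted
  out$significant_raw <- !is.na(out$p_raw) & out$p_raw < alpha
  out$significant_bh <- bh$significant
  out
}
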
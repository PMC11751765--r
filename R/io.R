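#' Read a daily gridded series table
#'
#' Long-format CSV interface for daily cubes: one row per (cell, day) with
#' a `cell_id` column, a `date` column (ISO dates) and one column per
#' variable.  `var_map` renames file columns onto the canonical names
#' (`sm`, `vpd`, `temperature`); a missing variable raises an error that
#' lists the columns actually present.  Each cell's calendar must advance
#' in strict 1-day steps.
#'
#' @param path CSV file (lines starting with `#` are provenance comments).
#' @param var_map named character vector: canonical name -> file column.
#' @return tibble with `cell_id`, `date` and the mapped variables.
#' @export
read_daily_series <- function(path,
                              var_map = c(sm = "sm", vpd = "vpd",
                                          temperature = "temperature")) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "date", unname(var_map))
  absent <- setdiff(need, names(d))
  if (length(absent))
    stop("file lacks column(s) ", paste(absent, collapse = ", "),
         "; available: ", paste(names(d), collapse = ", "))
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable dates in ", path)
  for (cid in unique(d$cell_id)) {
    dd <- sort(d$date[d$cell_id == cid])
    step <- unique(diff(as.integer(dd)))
    if (length(step) != 1 || step != 1L)
      stop("cell ", cid, " does not advance in daily steps ",
           "(observed steps: ", paste(utils::head(step, 5), collapse = ", "),
           ")")
  }
  out <- tibble::tibble(cell_id = d$cell_id, date = d$date)
  for (nm in names(var_map)) out[[nm]] <- as.numeric(d[[var_map[[nm]]]])
  out
}

provenance_line <- function(config_hash, seed) {
  sprintf("# smvpd provenance config_hash=%s seed=%d", config_hash, seed)
}

write_table_csv <- function(x, path, config_hash, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_line(config_hash, seed), con)
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (inherits(x[[j]], "Date"))
    x[[j]] <- format(x[[j]], "%Y-%m-%d")
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from JSON
#'
#' The file is a flat JSON object; recognized keys mirror the arguments of
#' [pipeline_config()] (unknown keys are rejected).
#'
#' @param path JSON file.
#' @return validated `smvpd_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), c(known, "synthetic"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$synthetic)) raw$synthetic <- do.call(synthetic_config,
                                                        raw$synthetic)
  do.call(pipeline_config, raw)
}

#' Run configuration for the full pipeline
#'
#' Bundles and validates every analysis threshold: the coupling lag and
#' window, the monthly missing-data rule (< 0.2), the growing-season
#' temperature threshold (5 degrees C), the attribution screens
#' (>= 20 samples, out-of-bag R-squared >= 0.2, slope p < 0.01) and the
#' binned covariate test levels (alpha 0.05, FDR 0.05).  Lags other than
#' 1, 7 or 14 days are rejected unless `allow_any_lag` is set.
#'
#' @param synthetic an [synthetic_config()] describing the input world (or
#'   `NULL` when a dataset is supplied to [run_pipeline()] directly).
#' @param lag coupling lag in days.
#' @param window moving-window length in days.
#' @param max_missing monthly missing-data tolerance.
#' @param temp_threshold growing-season threshold, degrees C.
#' @param min_samples,oob_threshold,alpha_slope attribution screens.
#' @param alpha_bins,fdr_q covariate-analysis levels.
#' @param aridity_edges,temp_edges spatial bin edges.
#' @param min_cells_bins,min_cells_covariate bin suppression rules
#'   (significant-cell count for bin means; total-cell count for the
#'   covariate tests).
#' @param seed seed forwarded to synthetic generation; model fitting keeps
#'   its own fixed random state (42) so the two streams never interact.
#' @param allow_any_lag lift the 1/7/14-day restriction.
#' @return validated list of class `smvpd_run_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            lag = 7L, window = 30L, max_missing = 0.2,
                            temp_threshold = 5, min_samples = 20L,
                            oob_threshold = 0.2, alpha_slope = 0.01,
                            alpha_bins = 0.05, fdr_q = 0.05,
                            aridity_edges = default_aridity_edges(),
                            temp_edges = default_temperature_edges(),
                            min_cells_bins = 10L,
                            min_cells_covariate = 20L,
                            seed = 1L, allow_any_lag = FALSE) {
  if (!allow_any_lag && !lag %in% c(1L, 7L, 14L))
    stop("lag must be 1, 7 or 14 days (set allow_any_lag to override)")
  if (max_missing <= 0 || max_missing > 1)
    stop("max_missing must lie in (0, 1]")
  for (a in c(alpha_slope, alpha_bins, fdr_q))
    if (a <= 0 || a >= 1) stop("significance levels must lie in (0, 1)")
  if (window < 2) stop("window must span at least 2 days")
  if (min_samples < 1 || min_cells_bins < 1 || min_cells_covariate < 1)
    stop("minimum-count rules must be positive")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "smvpd_config"))
  structure(list(synthetic = synthetic, lag = as.integer(lag),
                 window = as.integer(window), max_missing = max_missing,
                 temp_threshold = temp_threshold,
                 min_samples = as.integer(min_samples),
                 oob_threshold = oob_threshold, alpha_slope = alpha_slope,
                 alpha_bins = alpha_bins, fdr_q = fdr_q,
                 aridity_edges = aridity_edges, temp_edges = temp_edges,
                 min_cells_bins = as.integer(min_cells_bins),
                 min_cells_covariate = as.integer(min_cells_covariate),
                 seed = as.integer(seed), allow_any_lag = allow_any_lag),
            class = "smvpd_run_config")
}
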
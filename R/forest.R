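#' Fit the per-cell random-forest coupling model
#'
#' Regression random forest with the analysis' fixed hyperparameters:
#' 100 trees, bootstrap sampling, a random subset of
#' `max(1, floor(max_features * p))` candidate features at every split
#' (`max_features = 0.3`), and a fixed random state (42) so refits are
#' bit-identical.  Skill is the out-of-bag R-squared: every sample is
#' predicted by the trees whose bootstrap draw excluded it, and
#' `R2 = 1 - SSE/SST` with SST taken about the mean of the out-of-bag
#' targets.  A constant target gives `oob_r2 = NA` (the cell is screened
#' out downstream).
#'
#' @param table data frame holding the target and feature columns.
#' @param features character vector of feature column names.
#' @param target name of the target column.
#' @param ntree number of trees.
#' @param max_features fraction of features tried at each split.
#' @param min_leaf minimum samples per leaf (terminal-node size).
#' @param seed random state of the fit.
#' @return object of class `smvpd_rf` with elements `trees`, `oob_r2`,
#'   `oob_pred`, `features`, `n_samples`.
#' @export
fit_cell_model <- function(table, features, target = "pcor_monthly",
                           ntree = 100L, max_features = 0.3, min_leaf = 5L,
                           seed = 42L) {
  missing_cols <- setdiff(c(target, features), names(table))
  if (length(missing_cols))
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  table <- table[complete.cases(table[, c(target, features)]), , drop = FALSE]
  X <- as.matrix(table[, features, drop = FALSE])
  y <- as.numeric(table[[target]])
  if (nrow(X) < 2) stop("need at least 2 complete rows")
  mtry <- max(1L, as.integer(floor(max_features * length(features))))
  fit <- rf_fit_cpp(X, y, as.integer(ntree), mtry, as.integer(min_leaf),
                    as.integer(seed))
  structure(list(trees = fit$trees, oob_r2 = fit$oob_r2,
                 oob_pred = fit$oob_pred, n_oob = fit$n_oob,
                 features = features, target = target,
                 n_samples = nrow(X),
                 params = list(ntree = ntree, max_features = max_features,
                               mtry = mtry, min_leaf = min_leaf,
                               seed = seed)),
            class = "smvpd_rf")
}

#' @export
print.smvpd_rf <- function(x, ...) {
  cat(sprintf("<smvpd_rf> %d trees, %d samples, %d features, oob_r2 = %s\n",
              length(x$trees), x$n_samples, length(x$features),
              format(x$oob_r2, digits = 3)))
  invisible(x)
}

#' @export
predict.smvpd_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  rf_predict_cpp(object$trees, X)
}

#' Exact TreeSHAP decomposition of forest predictions
#'
#' Path-dependent TreeSHAP contributions of every feature to every row's
#' prediction.  Additivity holds exactly up to float rounding:
#' `base + rowSums(phi)` equals the forest prediction for each row.
#'
#' @param model an `smvpd_rf` fit.
#' @param table data frame with the model's feature columns (typically the
#'   pooled training table).
#' @return numeric matrix (rows x features) of contributions, with the
#'   forest expected value in attribute `base`.
#' @export
shap_decompose <- function(model, table) {
  stopifnot(inherits(model, "smvpd_rf"))
  X <- as.matrix(table[, model$features, drop = FALSE])
  if (anyNA(X)) stop("feature table contains missing values")
  res <- rf_shap_cpp(model$trees, X)
  phi <- res$phi
  colnames(phi) <- model$features
  attr(phi, "base") <- res$base
  phi
}
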
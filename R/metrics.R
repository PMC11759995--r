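# Held-out evaluation metrics. Metrics are computed on the normalized (0-1)
# target scale by default, which is the scale the loss is trained on; a flag
# reports original-scale values through the inverse normalization.

check_lengths <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length (", length(y), " vs ",
         length(yhat), ")")
  if (!length(y)) stop("empty input")
}

#' Root mean squared error
#' @param y observed values.
#' @param yhat predicted values.
#' @export
rmse <- function(y, yhat) {
  check_lengths(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; at most 1, negative for predictors worse than the
#' observed mean. Undefined (error) when `y` has zero variance.
#' @inheritParams rmse
#' @export
r_squared <- function(y, yhat) {
  check_lengths(y, yhat)
  if (length(y) < 2L) stop("r_squared needs at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r_squared undefined: zero variance in y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute error
#' @inheritParams rmse
#' @export
mae <- function(y, yhat) {
  check_lengths(y, yhat)
  mean(abs(y - yhat))
}

# short, dependency-free polynomial hash for provenance fields
config_fingerprint <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Evaluate a predictor on one split partition
#'
#' Computes RMSE, R-squared and MAE over exactly the mask-true cells of the
#' chosen partition. Any object with a [predict_cells()] method (the trained
#' network, the kriging/IDW/FNN baselines, external-regressor adapters) can
#' be evaluated.
#'
#' @param predictor fitted predictor.
#' @param grid a normalized `sample_grid`.
#' @param split a `dataset_split`.
#' @param partition one of `"train"`, `"validation"`, `"test"`.
#' @param scale `"normalized"` (default; matches the training loss scale) or
#'   `"original"` (inverted through the grid's normalization parameters).
#' @param method optional method label for the report.
#' @param seed optional provenance seed recorded in the report.
#' @return one-row data frame (`eval_report`): method, split, rmse, r2, mae,
#'   n, seed, fingerprint.
#' @export
evaluate <- function(predictor, grid, split, partition = "test",
                     scale = c("normalized", "original"),
                     method = class(predictor)[1], seed = NA_integer_) {
  scale <- match.arg(scale)
  cells <- split[[partition]]
  if (is.null(cells) || !nrow(cells))
    stop("partition '", partition, "' is empty or unknown")
  y <- grid$target[cells_lin(grid, cells)]
  yhat <- predict_cells(predictor, grid, cells)
  if (scale == "original") {
    y <- invert_normalization(y, grid$norm[["tph"]])
    yhat <- invert_normalization(yhat, grid$norm[["tph"]])
  }
  out <- data.frame(method = method, split = partition,
                    rmse = rmse(y, yhat), r2 = r_squared(y, yhat),
                    mae = mae(y, yhat), n = nrow(cells),
                    seed = seed,
                    fingerprint = config_fingerprint(list(method, predictor_config(predictor))))
  class(out) <- c("eval_report", "data.frame")
  out
}

predictor_config <- function(predictor) {
  if (inherits(predictor, "interp3d_network")) unclass(predictor$cfg)
  else if (!is.null(attr(predictor, "config"))) attr(predictor, "config")
  else class(predictor)
}

#' Write evaluation reports as delimiter-separated text
#' @param reports data frame of `eval_report` rows.
#' @param path output path.
#' @param sep delimiter.
#' @export
write_reports <- function(reports, path, sep = "\t") {
  utils::write.table(reports, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predict at a set of grid cells
#'
#' S3 generic tying every interpolation method (network or baseline) into
#' the shared [evaluate()] contract.
#'
#' @param object fitted predictor.
#' @param grid a normalized `sample_grid`.
#' @param cells integer cell matrix with columns `(d, r, c)`.
#' @return numeric vector of predictions on the normalized target scale.
#' @export
predict_cells <- function(object, grid, cells) UseMethod("predict_cells")

#' @export
predict_cells.interp3d_network <- function(object, grid, cells) {
  pred <- forward(object, grid)
  pred[cells_lin(grid, cells)]
}

#' @export
predict_cells.function <- function(object, grid, cells) {
  # plain function predictors: f(grid, cells) -> values (used in tests and
  # for oracle injection)
  object(grid, cells)
}
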
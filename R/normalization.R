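# Min-max normalization: x' = (x - x_min) / (x_max - x_min), fitted per
# feature on the training records only and applied with clipping elsewhere,
# so validation/test values never leak into the fitted extrema.

#' Fit per-feature min-max normalization parameters
#'
#' Scans the supplied records and stores the observed minimum and maximum of
#' every feature (and, by default, the `tph` target). A feature whose min and
#' max coincide cannot be rescaled to \[0,1\] and raises an error.
#'
#' @param records borehole record data frame (normally the training split).
#' @param features character vector of columns to fit; defaults to the nine
#'   feature channels plus the target.
#' @return object of class `normalization_params`: named list of
#'   `c(min, max)` pairs.
#' @export
fit_normalization <- function(records, features = c(borehole_features(), "tph")) {
  if (nrow(records) < 2L) stop("need at least 2 records to fit normalization")
  p <- lapply(features, function(f) {
    v <- records[[f]]
    if (is.null(v)) stop("feature '", f, "' not present in records")
    v <- v[is.finite(v)]
    if (!length(v)) stop("feature '", f, "' has no finite values")
    r <- range(v)
    if (r[1] == r[2])
      stop("degenerate feature '", f, "': min equals max (", r[1], ")")
    c(min = r[1], max = r[2])
  })
  names(p) <- features
  structure(p, class = "normalization_params")
}

#' Apply min-max normalization
#'
#' Affine map of `x` onto \[0,1\] using fitted extrema; values outside the
#' fitted range (possible on validation/test data) are clipped.
#'
#' @param x numeric vector.
#' @param p a `c(min, max)` pair (one element of [fit_normalization()]'s
#'   result).
#' @return numeric vector in \[0,1\].
#' @export
apply_normalization <- function(x, p) {
  if (p[["max"]] <= p[["min"]]) stop("invalid normalization params: max <= min")
  pmin(pmax((x - p[["min"]]) / (p[["max"]] - p[["min"]]), 0), 1)
}

#' Invert min-max normalization
#'
#' Exact affine inverse of [apply_normalization()] for in-range values,
#' recovering the original measurement scale.
#'
#' @inheritParams apply_normalization
#' @param x_norm numeric vector in \[0,1\].
#' @export
invert_normalization <- function(x_norm, p) {
  x_norm * (p[["max"]] - p[["min"]]) + p[["min"]]
}

#' Normalize a sample grid
#'
#' Applies fitted normalization to every feature channel and to the target
#' tensor of a [build_grid()] result. Masked cells keep their `NA` target
#' sentinel.
#'
#' @param grid a `sample_grid`.
#' @param params a `normalization_params` object covering all channels and
#'   `tph`.
#' @return the grid with `features` / `target` replaced by normalized tensors
#'   and `norm` recording the parameters used.
#' @export
normalize_grid <- function(grid, params) {
  stopifnot(inherits(grid, "sample_grid"))
  feats <- grid$raw_features
  for (ci in seq_along(grid$channels)) {
    ch <- grid$channels[ci]
    feats[, , , ci] <- apply_normalization(feats[, , , ci], params[[ch]])
  }
  tgt <- grid$raw_target
  obs <- is.finite(tgt)
  tgt[obs] <- apply_normalization(tgt[obs], params[["tph"]])
  grid$features <- feats
  grid$target <- tgt
  grid$norm <- params
  grid
}
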
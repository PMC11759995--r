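# Non-kriging baselines: inverse-distance weighting, a feed-forward network
# on the flat 9-feature vectors (no spatial tensor), and a pluggable adapter
# that lets any external fit/predict regressor enter the benchmark table.

#' Inverse-distance-weighted interpolation
#'
#' Weights proportional to `d^-p`; a query within 1e-12 of a sample returns
#' that sample's value exactly. Predictions are convex combinations of the
#' sample values, hence bounded by their range.
#'
#' @param points matrix: columns 1-3 are x, y, z; remaining column(s) the
#'   value(s) to interpolate.
#' @param query matrix with columns x, y, z.
#' @param power positive IDW exponent (default 2).
#' @return numeric vector (single value column) or matrix `(nq x nvalues)`.
#' @export
idw_predict <- function(points, query, power = 2) {
  if (power <= 0) stop("power must be > 0")
  points <- as.matrix(points); query <- matrix(as.numeric(as.matrix(query)), ncol = 3)
  if (nrow(points) < 1L) stop("need at least 1 point")
  vals <- points[, -(1:3), drop = FALSE]
  out <- matrix(NA_real_, nrow(query), ncol(vals))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(points[, 1:3, drop = FALSE]) - query[i, ])^2))
    hit <- which(d < 1e-12)
    if (length(hit)) {
      out[i, ] <- vals[hit[1], ]
    } else {
      w <- d^(-power)
      out[i, ] <- colSums(vals * w) / sum(w)
    }
  }
  if (ncol(out) == 1L) as.vector(out) else out
}

# -- feed-forward baseline ----------------------------------------------------
# Dense MLP trained with the same masked-MSE / Adam / plateau recipe as the
# main model, but on flat per-sample feature vectors.

dense_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fi <- sizes[i]; fo <- sizes[i + 1L]
    lim <- sqrt(6 / (fi + fo))
    list(W = matrix(stats::runif(fi * fo, -lim, lim), fo, fi),
         b = numeric(fo))
  })
}

dense_forward <- function(layers, X, activation) {
  # X: n x p; hidden layers use `activation`, output layer is linear
  a <- t(X); caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    pre <- layers[[i]]$W %*% a + layers[[i]]$b
    caches[[i]] <- list(a_in = a, pre = pre)
    a <- if (i < length(layers)) act_apply(pre, activation) else pre
  }
  list(out = as.vector(a), caches = caches)
}

dense_backward <- function(layers, caches, dOut, activation) {
  # dOut: vector over samples (gradient wrt linear output)
  grads <- vector("list", length(layers))
  da <- matrix(dOut, nrow = 1)
  for (i in rev(seq_along(layers))) {
    dpre <- if (i < length(layers))
      da * act_grad(caches[[i]]$pre, activation) else da
    grads[[i]] <- list(W = dpre %*% t(caches[[i]]$a_in),
                       b = rowSums(dpre))
    da <- crossprod(layers[[i]]$W, dpre)
  }
  grads
}

#' Feed-forward network baseline
#'
#' Fully connected regressor on the flat feature vectors (default hidden
#' sizes 64 and 32, Tanh), trained full-batch with Adam, masked MSE and the
#' same reduce-on-plateau schedule as the 3D network.
#'
#' @param X training feature matrix (n x p, normalized).
#' @param y training targets (normalized).
#' @param Xval,yval validation data driving the plateau schedule and best-
#'   weight selection.
#' @param hidden integer vector of hidden-layer sizes.
#' @param activation hidden activation.
#' @param cfg a [train_config()].
#' @return object of class `fnn` with a `predict` closure.
#' @export
fnn_baseline <- function(X, y, Xval, yval, hidden = c(64, 32),
                         activation = "tanh", cfg = train_config()) {
  X <- as.matrix(X); Xval <- as.matrix(Xval)
  sizes <- c(ncol(X), hidden, 1L)
  with_seed(cfg$seed, {
    layers <- dense_init(sizes)
    flat <- function(ls) unlist(lapply(ls, function(l) list(l$W, l$b)),
                                recursive = FALSE)
    params <- flat(layers)
    state <- adam_init(stats::setNames(params, paste0("p", seq_along(params))))
    names(params) <- paste0("p", seq_along(params))
    lr <- cfg$learning_rate
    best_val <- Inf; wait <- 0L; best_params <- params
    n <- nrow(X)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), lr = numeric())
    rebuild <- function(params) {
      k <- 1L
      for (i in seq_along(layers)) {
        layers[[i]]$W <- params[[k]]; layers[[i]]$b <- params[[k + 1L]]
        k <- k + 2L
      }
      layers
    }
    for (epoch in seq_len(cfg$epochs)) {
      layers <- rebuild(params)
      fw <- dense_forward(layers, X, activation)
      resid <- fw$out - y
      train_loss <- mean(resid^2)
      if (!is.finite(train_loss))
        stop("non-finite FNN training loss at epoch ", epoch)
      g <- dense_backward(layers, fw$caches, 2 * resid / n, activation)
      grads <- stats::setNames(flat(g), names(params))
      upd <- adam_step(params, grads, state, lr, cfg)
      params <- upd$params; state <- upd$state
      val_loss <- mean((dense_forward(rebuild(params), Xval, activation)$out - yval)^2)
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; wait <- 0L; best_params <- params
      } else {
        wait <- wait + 1L
        if (wait >= cfg$plateau_patience) {
          lr <- max(lr * cfg$plateau_factor, cfg$min_lr); wait <- 0L
        }
      }
      hist[epoch, ] <- list(epoch, train_loss, val_loss, lr)
    }
    layers <- rebuild(best_params)
    obj <- structure(
      list(layers = layers, activation = activation, hidden = hidden,
           history = hist),
      class = "fnn",
      config = list(hidden = hidden, activation = activation,
                    seed = cfg$seed))
    obj
  })
}

#' Predict with a fitted FNN baseline
#' @param object an `fnn`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.fnn <- function(object, newdata, ...) {
  dense_forward(object$layers, as.matrix(newdata), object$activation)$out
}

#' Wrap an external regressor for the benchmark table
#'
#' Any object exposing `fit(features, targets)` and `predict(features)` can
#' enter the evaluation protocol through this adapter (this is how an SVR or
#' random-forest regressor from another package joins the comparison without
#' the package re-deriving its optimizer).
#'
#' @param name method label used in reports.
#' @param fit function `(X, y) -> fitted state`.
#' @param predict function `(state, X) -> numeric predictions`.
#' @return object of class `regressor_adapter`.
#' @export
external_regressor_adapter <- function(name, fit, predict) {
  if (!is.function(fit) || !is.function(predict))
    stop("adapter contract violated: fit and predict must be functions")
  structure(list(name = name, fit = fit, predict = predict, state = NULL),
            class = "regressor_adapter",
            config = list(name = name))
}

adapter_fit <- function(adapter, X, y) {
  adapter$state <- adapter$fit(X, y)
  adapter
}

adapter_predict <- function(adapter, X) {
  out <- adapter$predict(adapter$state, X)
  if (!is.numeric(out) || length(out) != nrow(X))
    stop("adapter contract violated: predict must return one numeric value ",
         "per query row (got length ", length(out), " for ", nrow(X), " rows)")
  as.numeric(out)
}

# -- predict_cells bindings ---------------------------------------------------

#' @export
predict_cells.kriging_system <- function(object, grid, cells) {
  kriging3d_predict(object, cell_coords(grid, cells))$prediction
}

#' @export
predict_cells.idw_interpolator <- function(object, grid, cells) {
  idw_predict(object$points, cell_coords(grid, cells), power = object$power)
}

#' @export
predict_cells.fnn <- function(object, grid, cells) {
  predict(object, cell_features(grid, cells))
}

#' @export
predict_cells.regressor_adapter <- function(object, grid, cells) {
  adapter_predict(object, cell_features(grid, cells))
}
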
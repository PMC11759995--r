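# Encoder-decoder 3D convolutional interpolation network.
#
# Encoder: three valid (stride-1, no padding) 3D convolutions with ReLU, each
# optionally followed by a channel-attention block. Decoder: dropout, then
# three transposed 3D convolutions with Tanh; the final transpose kernel is
# solved at build time so the output spatial shape equals the input spatial
# shape exactly (the build fails loudly if no valid kernel exists). The
# network maps a (D, m, n, T) normalized feature tensor to a (D, m, n) map of
# predicted normalized concentration.

#' Model configuration for the 3D interpolation network
#'
#' @param encoder_filters output channels of the encoder convolutions.
#' @param encoder_kernels list of `(kd, kh, kw)` encoder kernel extents.
#' @param decoder_kernels list of `(kd, kh, kw)` transpose kernel extents; a
#'   `NULL` entry (default: the last) is solved at build time so the decoder
#'   restores the input spatial shape.
#' @param reduction_ratio channel-attention MLP bottleneck divisor.
#' @param mlp_activation channel-attention MLP hidden activation.
#' @param dropout_rate dropout probability applied before the first
#'   transposed convolution (training mode only).
#' @param hidden_activation activation of the decoder / transpose stages.
#' @param conv_inner_activation activation inside encoder convolutions.
#' @param use_cam if `FALSE` the attention blocks are identity (ablation).
#' @param use_batchnorm apply per-channel batch normalization after every
#'   convolution and after every non-final transposed convolution (the final
#'   transpose stage is the regression head and is left un-normalized).
#'   Off by default: with full-batch training on a single grid tensor the
#'   batch statistics degenerate to per-grid spatial statistics, and at the
#'   ~100-training-cell scale this model targets the extra normalization
#'   layers encourage memorization (see the methods vignette).
#' @param bn_momentum exponential momentum of the running statistics used at
#'   inference.
#' @param collapse_depth if `TRUE` all kernel depth extents are forced to 1,
#'   removing convolution across depth (the "2D CNN" ablation variant).
#' @param seed integer seed governing weight initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(encoder_filters = c(16, 32, 64),
                         encoder_kernels = list(c(2, 2, 2), c(2, 2, 2), c(1, 2, 1)),
                         decoder_kernels = list(c(1, 2, 1), c(1, 2, 2), NULL),
                         reduction_ratio = 2,
                         mlp_activation = "relu",
                         dropout_rate = 0.2,
                         hidden_activation = "tanh",
                         conv_inner_activation = "relu",
                         use_cam = TRUE,
                         use_batchnorm = FALSE,
                         bn_momentum = 0.1,
                         collapse_depth = FALSE,
                         seed = 1L) {
  if (length(encoder_filters) != length(encoder_kernels))
    stop("encoder_filters and encoder_kernels must have the same length")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (collapse_depth) {
    encoder_kernels <- lapply(encoder_kernels, function(k) c(1L, k[2], k[3]))
    decoder_kernels <- lapply(decoder_kernels, function(k)
      if (is.null(k)) NULL else c(1L, k[2], k[3]))
  }
  structure(list(encoder_filters = as.integer(encoder_filters),
                 encoder_kernels = lapply(encoder_kernels, as.integer),
                 decoder_kernels = decoder_kernels,
                 reduction_ratio = reduction_ratio,
                 mlp_activation = mlp_activation,
                 dropout_rate = dropout_rate,
                 hidden_activation = hidden_activation,
                 conv_inner_activation = conv_inner_activation,
                 use_cam = isTRUE(use_cam),
                 use_batchnorm = isTRUE(use_batchnorm),
                 bn_momentum = bn_momentum,
                 collapse_depth = isTRUE(collapse_depth),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build the 3D-CNN + channel-attention interpolation network
#'
#' Resolves all layer shapes for the given input, solves the final transpose
#' kernel so the decoder restores `(D, m, n)`, and initializes all weights
#' deterministically from `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @param input_shape integer vector `(D, m, n, T)`.
#' @return object of class `interp3d_network`.
#' @export
build_interpolator <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "model_config"), length(input_shape) == 4L)
  input_shape <- as.integer(input_shape)
  spatial <- input_shape[1:3]
  shape <- spatial
  nenc <- length(cfg$encoder_filters)
  enc_shapes <- vector("list", nenc)
  for (i in seq_len(nenc)) {
    k <- cfg$encoder_kernels[[i]]
    if (any(k > shape))
      stop("configuration error at encoder stage ", i, ": kernel ",
           paste(k, collapse = "x"), " does not fit feature map ",
           paste(shape, collapse = "x"))
    shape <- shape - k + 1L
    enc_shapes[[i]] <- shape
  }
  ndec <- length(cfg$decoder_kernels)
  dec_kernels <- cfg$decoder_kernels
  for (i in seq_len(ndec)) {
    k <- dec_kernels[[i]]
    if (is.null(k)) {
      if (i < ndec) stop("only the final decoder kernel may be solved (NULL)")
      k <- spatial - shape + 1L
      if (any(k < 1L))
        stop("configuration error at decoder stage ", i,
             ": feature map ", paste(shape, collapse = "x"),
             " already exceeds target ", paste(spatial, collapse = "x"))
      dec_kernels[[i]] <- as.integer(k)
    }
    shape <- shape + as.integer(k) - 1L
  }
  if (!all(shape == spatial))
    stop("configuration error: decoder output spatial shape ",
         paste(shape, collapse = "x"), " != input spatial shape ",
         paste(spatial, collapse = "x"),
         " (set the final decoder kernel to NULL to have it solved)")

  layers <- with_seed(cfg$seed, {
    ls <- list()
    cin <- input_shape[4]
    cur <- input_shape
    for (i in seq_len(nenc)) {
      k <- cfg$encoder_kernels[[i]]; cout <- cfg$encoder_filters[i]
      fan_in <- prod(k) * cin; fan_out <- prod(k) * cout
      ls[[length(ls) + 1L]] <- list(
        type = "conv", kernel = k,
        W = glorot(c(k, cin, cout), fan_in, fan_out), b = numeric(cout),
        activation = if (cfg$use_batchnorm) "identity" else cfg$conv_inner_activation,
        im2col = im2col_indices(cur, c(k, cin, cout)))
      cur <- c(cur[1:3] - k + 1L, cout)
      if (cfg$use_batchnorm)
        ls[[length(ls) + 1L]] <- list(
          type = "bn", gamma = rep(1, cout), beta = numeric(cout),
          running_mean = numeric(cout), running_var = rep(1, cout),
          momentum = cfg$bn_momentum, activation = cfg$conv_inner_activation)
      ls[[length(ls) + 1L]] <- list(
        type = "cam", identity = !cfg$use_cam,
        weights = cam_init(cout, cfg$reduction_ratio, cfg$mlp_activation))
      cin <- cout
    }
    ls[[length(ls) + 1L]] <- list(type = "dropout", rate = cfg$dropout_rate)
    for (i in seq_len(ndec)) {
      k <- as.integer(dec_kernels[[i]])
      cout <- if (i == ndec) 1L else rev(cfg$encoder_filters)[i + 1L]
      fan_in <- prod(k) * cin; fan_out <- prod(k) * cout
      padded <- c(cur[1:3] + 2L * (k - 1L), cin)
      final <- i == ndec
      ls[[length(ls) + 1L]] <- list(
        type = "tconv", kernel = k,
        W = glorot(c(k, cin, cout), fan_in, fan_out), b = numeric(cout),
        activation = if (cfg$use_batchnorm && !final) "identity"
                     else cfg$hidden_activation,
        im2col = im2col_indices(padded, c(k, cin, cout)))
      cur <- c(cur[1:3] + k - 1L, cout)
      if (cfg$use_batchnorm && !final)
        ls[[length(ls) + 1L]] <- list(
          type = "bn", gamma = rep(1, cout), beta = numeric(cout),
          running_mean = numeric(cout), running_var = rep(1, cout),
          momentum = cfg$bn_momentum, activation = cfg$hidden_activation)
      cin <- cout
    }
    ls
  })

  structure(list(cfg = cfg, input_shape = input_shape,
                 decoder_kernels = dec_kernels, layers = layers),
            class = "interp3d_network")
}

#' @export
print.interp3d_network <- function(x, ...) {
  cat("interp3d_network: input (", paste(x$input_shape, collapse = ", "),
      "), ", length(x$layers), " layers",
      if (!x$cfg$use_cam) ", CAM disabled", "\n", sep = "")
  invisible(x)
}

net_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      r <- conv3d_gemm(x, layer$W, layer$b, layer$activation, layer$im2col)
      x <- r$out
      if (keep_cache) caches[[li]] <- r$cache
    } else if (layer$type == "cam") {
      if (layer$identity) {
        if (keep_cache) caches[[li]] <- list(identity = TRUE)
      } else {
        r <- channel_attention(x, layer$weights, keep_cache = keep_cache)
        x <- r$out
        if (keep_cache) caches[[li]] <- r$cache
      }
    } else if (layer$type == "bn") {
      # statistics are always those of the current input: the model trains
      # full-batch on one grid tensor, so the batch is the population and
      # using stored moments would only reintroduce a train/inference gap
      r <- bn_forward(x, layer$gamma, layer$beta, layer$running_mean,
                      layer$running_var, train = TRUE,
                      momentum = layer$momentum)
      pre <- r$out
      x <- act_apply(pre, layer$activation)
      if (keep_cache)
        caches[[li]] <- list(bn = r$cache, pre = pre,
                             new_rm = r$running_mean, new_rv = r$running_var)
    } else if (layer$type == "dropout") {
      if (train && layer$rate > 0) {
        keep <- array(stats::rbinom(length(x), 1L, 1 - layer$rate),
                      dim = dim(x)) / (1 - layer$rate)
        x <- x * keep
        if (keep_cache) caches[[li]] <- list(keep = keep)
      } else if (keep_cache) caches[[li]] <- list(keep = NULL)
    } else if (layer$type == "tconv") {
      r <- tconv3d(x, layer$W, layer$b, layer$activation, layer$im2col)
      x <- r$out
      if (keep_cache) caches[[li]] <- r$cache
    }
  }
  if (keep_cache) list(out = x, caches = caches) else x
}

net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      g <- conv3d_gemm_backward(dOut, caches[[li]])
      grads[[li]] <- list(W = g$dW, b = g$db)
      dOut <- g$dX
    } else if (layer$type == "cam") {
      if (layer$identity) next
      g <- cam_backward(dOut, caches[[li]], layer$weights)
      grads[[li]] <- list(W1 = g$dW1, b1 = g$db1, W2 = g$dW2, b2 = g$db2)
      dOut <- g$dX
    } else if (layer$type == "bn") {
      dPre <- dOut * act_grad(caches[[li]]$pre, layer$activation)
      g <- bn_backward(dPre, caches[[li]]$bn)
      grads[[li]] <- list(gamma = g$dgamma, beta = g$dbeta)
      dOut <- g$dX
    } else if (layer$type == "dropout") {
      if (!is.null(caches[[li]]$keep)) dOut <- dOut * caches[[li]]$keep
    } else if (layer$type == "tconv") {
      g <- tconv3d_backward(dOut, caches[[li]])
      grads[[li]] <- list(W = g$dW, b = g$db)
      dOut <- g$dX
    }
  }
  grads
}

net_params <- function(net) {
  out <- list()
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type %in% c("conv", "tconv")) {
      out[[paste0("L", li, ".W")]] <- layer$W
      out[[paste0("L", li, ".b")]] <- layer$b
    } else if (layer$type == "cam" && !layer$identity) {
      for (p in c("W1", "b1", "W2", "b2"))
        out[[paste0("L", li, ".", p)]] <- layer$weights[[p]]
    } else if (layer$type == "bn") {
      out[[paste0("L", li, ".gamma")]] <- layer$gamma
      out[[paste0("L", li, ".beta")]] <- layer$beta
    }
  }
  out
}

net_set_params <- function(net, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    li <- as.integer(sub("^L", "", parts[1])); p <- parts[2]
    if (net$layers[[li]]$type == "cam")
      net$layers[[li]]$weights[[p]] <- params[[nm]]
    else net$layers[[li]][[p]] <- params[[nm]]
  }
  net
}

get_bn_stats <- function(net) {
  out <- list()
  for (li in seq_along(net$layers))
    if (net$layers[[li]]$type == "bn")
      out[[paste0("L", li)]] <- list(running_mean = net$layers[[li]]$running_mean,
                                     running_var = net$layers[[li]]$running_var)
  out
}

set_bn_stats <- function(net, stats) {
  for (nm in names(stats)) {
    li <- as.integer(sub("^L", "", nm))
    net$layers[[li]]$running_mean <- stats[[nm]]$running_mean
    net$layers[[li]]$running_var <- stats[[nm]]$running_var
  }
  net
}

grads_as_params <- function(net, grads) {
  out <- list()
  for (li in seq_along(grads)) {
    if (is.null(grads[[li]])) next
    g <- grads[[li]]
    if (!is.null(g$W)) { out[[paste0("L", li, ".W")]] <- g$W
                         out[[paste0("L", li, ".b")]] <- g$b }
    else if (!is.null(g$gamma)) { out[[paste0("L", li, ".gamma")]] <- g$gamma
                                  out[[paste0("L", li, ".beta")]] <- g$beta }
    else for (p in c("W1", "b1", "W2", "b2"))
      out[[paste0("L", li, ".", p)]] <- g[[p]]
  }
  out
}

#' Run the interpolation network forward
#'
#' Inference-mode forward pass (dropout disabled, deterministic): returns the
#' predicted normalized concentration at every grid cell, including masked
#' cells (the mask only restricts losses and metrics).
#'
#' @param network an `interp3d_network`.
#' @param grid a normalized `sample_grid`, or a raw `(D, m, n, T)` feature
#'   array.
#' @return numeric array `(D, m, n)`.
#' @export
forward <- function(network, grid) {
  x <- if (inherits(grid, "sample_grid")) {
    if (is.null(grid$features)) stop("grid is not normalized")
    grid$features
  } else grid
  if (dim(x)[4] != network$input_shape[4])
    stop("feature channels (", dim(x)[4], ") != network input channels (",
         network$input_shape[4], ")")
  out <- net_forward(network, x, train = FALSE)
  array(out, dim = dim(out)[1:3])
}
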
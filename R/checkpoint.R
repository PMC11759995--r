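# Versioned JSON checkpoints. Weight tensors are stored as full-precision
# ("%.17g") decimal strings so save -> load -> forward is bit-for-bit equal
# to the original network in inference mode.

CHECKPOINT_FORMAT_VERSION <- 1L

#' Save a trained network as a checkpoint
#'
#' The checkpoint bundles the model configuration, all weights, and the
#' normalization parameters, so prediction on raw borehole records works end
#' to end after loading.
#'
#' @param network an `interp3d_network`.
#' @param normalization a `normalization_params` object.
#' @param path optional file path; if given, the checkpoint is written as
#'   JSON.
#' @return checkpoint object (invisibly, if written to a file).
#' @export
save_checkpoint <- function(network, normalization, path = NULL) {
  params <- net_params(network)
  ck <- list(
    format_version = CHECKPOINT_FORMAT_VERSION,
    config = unclass(network$cfg),
    input_shape = network$input_shape,
    decoder_kernels = network$decoder_kernels,
    weights = lapply(params, function(p)
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = num2str(as.vector(p)))),
    bn_stats = lapply(get_bn_stats(network), function(s)
      list(running_mean = num2str(s$running_mean),
           running_var = num2str(s$running_var))),
    normalization = lapply(normalization, num2str)
  )
  class(ck) <- "interp3d_checkpoint"
  if (!is.null(path)) {
    jsonlite::write_json(unclass(ck), path, auto_unbox = TRUE, null = "null")
    return(invisible(ck))
  }
  ck
}

#' Load a checkpoint and rebuild the network
#'
#' @param checkpoint an `interp3d_checkpoint` object or a path to a
#'   checkpoint JSON file.
#' @return list with `network` (forward-identical to the saved one) and
#'   `normalization`.
#' @export
load_checkpoint <- function(checkpoint) {
  if (is.character(checkpoint)) {
    ck <- tryCatch(jsonlite::read_json(checkpoint, simplifyVector = TRUE),
                   error = function(e) stop("cannot read checkpoint: ",
                                            conditionMessage(e)))
  } else ck <- unclass(checkpoint)
  if (is.null(ck$format_version) ||
      !identical(as.integer(ck$format_version), CHECKPOINT_FORMAT_VERSION))
    stop("unsupported checkpoint format version: ",
         ck$format_version %||% "<missing>")
  if (is.null(ck$weights) || is.null(ck$config))
    stop("checkpoint payload is truncated or corrupt")
  cfgl <- ck$config
  cfg <- model_config(
    encoder_filters = unlist(cfgl$encoder_filters),
    encoder_kernels = lapply(as_kernel_list(cfgl$encoder_kernels), identity),
    decoder_kernels = as_kernel_list(ck$decoder_kernels),
    reduction_ratio = cfgl$reduction_ratio,
    mlp_activation = cfgl$mlp_activation,
    dropout_rate = cfgl$dropout_rate,
    hidden_activation = cfgl$hidden_activation,
    conv_inner_activation = cfgl$conv_inner_activation,
    use_cam = cfgl$use_cam,
    use_batchnorm = cfgl$use_batchnorm %||% TRUE,
    bn_momentum = cfgl$bn_momentum %||% 0.1,
    collapse_depth = FALSE,  # kernels above are already collapsed if needed
    seed = cfgl$seed)
  net <- build_interpolator(cfg, unlist(ck$input_shape))
  params <- lapply(ck$weights, function(w) {
    dm <- unlist(w$dim)
    v <- str2num(unlist(w$data))
    if (length(v) != prod(dm)) stop("checkpoint payload is truncated or corrupt")
    if (length(dm) > 1L) array(v, dim = dm) else v
  })
  net <- net_set_params(net, params)
  if (!is.null(ck$bn_stats))
    net <- set_bn_stats(net, lapply(ck$bn_stats, function(s)
      list(running_mean = str2num(unlist(s$running_mean)),
           running_var = str2num(unlist(s$running_var)))))
  norm <- structure(lapply(ck$normalization, function(p)
    stats::setNames(str2num(unlist(p)), c("min", "max"))),
    class = "normalization_params")
  list(network = net, normalization = norm)
}

as_kernel_list <- function(x) {
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  lapply(x, unlist)
}
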
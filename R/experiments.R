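# Orchestrated experiments: the method-comparison benchmark, the
# channel-attention ablation, the per-feature ablation, and dense prediction
# maps. Stochastic methods are replicated over seeds and aggregated by
# medians; every table row carries a config fingerprint for provenance.

CNN_VARIANTS <- c("cnn3d_cam", "cnn3d", "cnn2d")
ALL_METHODS <- c("kriging3d", "idw", "fnn", CNN_VARIANTS)

cnn_variant_config <- function(variant, model_cfg = model_config()) {
  switch(variant,
    cnn3d_cam = model_cfg,
    cnn3d = { model_cfg$use_cam <- FALSE; model_cfg },
    cnn2d = {
      cfg <- model_config(
        encoder_filters = model_cfg$encoder_filters,
        encoder_kernels = model_cfg$encoder_kernels,
        decoder_kernels = model_cfg$decoder_kernels,
        reduction_ratio = model_cfg$reduction_ratio,
        mlp_activation = model_cfg$mlp_activation,
        dropout_rate = model_cfg$dropout_rate,
        hidden_activation = model_cfg$hidden_activation,
        conv_inner_activation = model_cfg$conv_inner_activation,
        use_cam = FALSE, collapse_depth = TRUE, seed = model_cfg$seed)
      cfg
    },
    stop("unknown CNN variant: ", variant))
}

default_variogram_bins <- function(coords, nbins = 8L) {
  dmax <- max(stats::dist(coords))
  seq(0, dmax * 1.001, length.out = nbins + 1L)
}

#' Fit one interpolation method on a prepared dataset
#'
#' Shared entry point of the benchmark: fits any of `kriging3d`, `idw`,
#' `fnn`, `cnn2d`, `cnn3d`, `cnn3d_cam` on the train partition and returns a
#' predictor usable with [evaluate()].
#'
#' @param method method name.
#' @param grid normalized `sample_grid`.
#' @param split `dataset_split`.
#' @param seed seed for stochastic fits (network initialization/training).
#' @param model_cfg base [model_config()] for the CNN variants.
#' @param train_cfg [train_config()] for the trained methods.
#' @param variogram_family family for the kriging baseline.
#' @param adapter optional `regressor_adapter` (required when
#'   `method = "adapter"`).
#' @return fitted predictor.
#' @export
fit_method <- function(method, grid, split, seed = 1L,
                       model_cfg = model_config(),
                       train_cfg = train_config(),
                       variogram_family = "spherical",
                       adapter = NULL) {
  tr <- split$train
  coords <- cell_coords(grid, tr)
  ytr <- grid$target[cells_lin(grid, tr)]
  if (method == "kriging3d") {
    emp <- empirical_variogram(cbind(coords, ytr),
                               default_variogram_bins(coords))
    model <- tryCatch(fit_variogram(emp, variogram_family),
                      warning = function(w) suppressWarnings(
                        fit_variogram(emp, variogram_family)))
    kriging_fit(coords, ytr, model)
  } else if (method == "idw") {
    structure(list(points = cbind(coords, ytr), power = 2),
              class = "idw_interpolator",
              config = list(power = 2))
  } else if (method == "fnn") {
    va <- split$validation
    cfg <- train_cfg; cfg$seed <- as.integer(seed)
    fnn_baseline(cell_features(grid, tr), ytr,
                 cell_features(grid, va),
                 grid$target[cells_lin(grid, va)],
                 cfg = cfg)
  } else if (method %in% CNN_VARIANTS) {
    mc <- cnn_variant_config(method, model_cfg)
    mc$seed <- as.integer(seed)
    tc <- train_cfg; tc$seed <- as.integer(seed)
    net <- build_interpolator(mc, dim(grid$features))
    train(net, grid, split, tc)$network
  } else if (method == "adapter") {
    if (is.null(adapter)) stop("method 'adapter' needs an adapter object")
    adapter_fit(adapter, cell_features(grid, tr), ytr)
  } else stop("unknown method name: ", method)
}

#' Method-comparison benchmark on one prepared dataset
#'
#' Fits every requested method once per seed and evaluates it on the
#' validation and test partitions; per-method medians over seeds are
#' reported alongside the raw rows.
#'
#' @inheritParams fit_method
#' @param methods character vector of method names.
#' @param seeds integer vector of fitting seeds.
#' @param adapters named list of `regressor_adapter` objects appended as
#'   additional methods.
#' @return list with `reports` (one row per method x seed x partition) and
#'   `summary` (median metrics per method on the test partition).
#' @export
run_benchmark <- function(grid, split, methods = ALL_METHODS,
                          seeds = 1:5,
                          model_cfg = model_config(),
                          train_cfg = train_config(epochs = 150L),
                          adapters = list()) {
  bad <- setdiff(methods, ALL_METHODS)
  if (length(bad)) stop("unknown method name: ", paste(bad, collapse = ", "))
  rows <- list()
  for (method in methods) {
    deterministic <- method %in% c("kriging3d", "idw")
    use_seeds <- if (deterministic) seeds[1] else seeds
    for (s in use_seeds) {
      fitted <- fit_method(method, grid, split, seed = s,
                           model_cfg = model_cfg, train_cfg = train_cfg)
      for (part in c("validation", "test"))
        rows[[length(rows) + 1L]] <-
          evaluate(fitted, grid, split, part, method = method, seed = s)
    }
  }
  for (nm in names(adapters)) {
    fitted <- fit_method("adapter", grid, split, adapter = adapters[[nm]])
    for (part in c("validation", "test"))
      rows[[length(rows) + 1L]] <-
        evaluate(fitted, grid, split, part, method = nm, seed = seeds[1])
  }
  reports <- do.call(rbind, rows)
  list(reports = reports, summary = summarize_reports(reports))
}

summarize_reports <- function(reports, partition = "test") {
  sub <- reports[reports$split == partition, , drop = FALSE]
  out <- do.call(rbind, lapply(split(sub, sub$method), function(g)
    data.frame(method = g$method[1],
               r2 = stats::median(g$r2), rmse = stats::median(g$rmse),
               mae = stats::median(g$mae), n_runs = nrow(g))))
  out[order(-out$r2), , drop = FALSE]
}

#' Replicated benchmark over fresh synthetic fields
#'
#' Generates a new synthetic field (and a new 7:2:1 split) per seed, fits
#' the methods, and aggregates per-method medians on the test partition —
#' the replication protocol used to compare method orderings without relying
#' on a single realization.
#'
#' @param preset scenario preset name (see [scenario_presets()]).
#' @param seeds integer vector; one field + fit per seed.
#' @inheritParams run_benchmark
#' @return list with `reports` and `summary`.
#' @export
run_scenario_benchmark <- function(preset = "paperlike", seeds = 1:10,
                                   methods = ALL_METHODS,
                                   model_cfg = model_config(),
                                   train_cfg = train_config(epochs = 150L)) {
  rows <- list()
  for (s in seeds) {
    params <- scenario_params(preset, seed = s)
    records <- generate_field(params)
    ds <- prepare_dataset(records, m = params$m, n = params$n,
                          depth_edges = params$depth_edges, seed = s)
    for (method in methods) {
      fitted <- fit_method(method, ds$grid, ds$split, seed = s,
                           model_cfg = model_cfg, train_cfg = train_cfg)
      for (part in c("validation", "test"))
        rows[[length(rows) + 1L]] <-
          evaluate(fitted, ds$grid, ds$split, part, method = method, seed = s)
    }
  }
  reports <- do.call(rbind, rows)
  list(reports = reports, summary = summarize_reports(reports))
}

#' Channel-attention ablation
#'
#' Trains the three CNN variants (`cnn2d`, `cnn3d`, `cnn3d_cam`) with
#' identical seeds and otherwise identical configurations, so differences
#' are attributable only to the ablated component.
#'
#' @inheritParams run_benchmark
#' @export
run_cam_ablation <- function(grid, split, seeds = 1:5,
                             model_cfg = model_config(),
                             train_cfg = train_config(epochs = 150L)) {
  run_benchmark(grid, split, methods = CNN_VARIANTS, seeds = seeds,
                model_cfg = model_cfg, train_cfg = train_cfg)
}

#' Per-feature ablation
#'
#' Retrains the attention CNN with one covariate channel removed at a time
#' (tensor rebuilt with T-1 channels, same seeds), plus the all-features
#' reference row.
#'
#' @inheritParams run_benchmark
#' @param features covariate channel names to drop, one per run.
#' @return list with `reports` and `summary` (one row per dropped feature
#'   plus `"all"`).
#' @export
run_feature_ablation <- function(grid, split, features, seeds = 1:5,
                                 model_cfg = model_config(),
                                 train_cfg = train_config(epochs = 150L)) {
  bad <- setdiff(features, grid$channels)
  if (length(bad)) stop("cannot drop unknown feature(s): ",
                        paste(bad, collapse = ", "))
  rows <- list()
  variants <- c(list(all = grid),
                stats::setNames(lapply(features, function(f)
                  drop_channel(grid, f)), features))
  for (nm in names(variants)) {
    g <- variants[[nm]]
    for (s in seeds) {
      fitted <- fit_method("cnn3d_cam", g, split, seed = s,
                           model_cfg = model_cfg, train_cfg = train_cfg)
      rep <- evaluate(fitted, g, split, "test", method = nm, seed = s)
      rep$dropped <- nm
      rows[[length(rows) + 1L]] <- rep
    }
  }
  reports <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(reports, reports$dropped), function(g)
    data.frame(dropped = g$dropped[1], r2 = stats::median(g$r2),
               rmse = stats::median(g$rmse), mae = stats::median(g$mae))))
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}

# -- dense prediction maps ----------------------------------------------------

#' Write a matrix as an ESRI ASCII grid
#'
#' @param mat numeric matrix; row 1 is the northernmost row.
#' @param path output path (conventionally `.asc`).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize square cell size.
#' @param nodata NODATA sentinel.
#' @export
write_esri_ascii <- function(mat, path, xllcorner, yllcorner, cellsize,
                             nodata = -9999) {
  hdr <- c(paste("ncols", ncol(mat)),
           paste("nrows", nrow(mat)),
           paste("xllcorner", format(xllcorner, scientific = FALSE)),
           paste("yllcorner", format(yllcorner, scientific = FALSE)),
           paste("cellsize", format(cellsize, scientific = FALSE)),
           paste("NODATA_value", nodata))
  m <- mat
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Dense prediction map from a trained checkpoint
#'
#' Builds a dense query lattice, obtains the soil covariates at unsampled
#' cells by inverse-distance weighting (power 2) from the borehole records,
#' runs the network, and returns per-depth-layer 2D prediction grids on the
#' original concentration scale. Optionally writes one ESRI ASCII grid per
#' depth layer plus a JSON metadata sidecar (seed, fingerprint, version,
#' extrapolation flag).
#'
#' @param checkpoint an `interp3d_checkpoint` (or path) from
#'   [save_checkpoint()].
#' @param records borehole records supplying covariates.
#' @param m,n dense lattice rows/columns.
#' @param depth_edges depth bin edges of the query lattice.
#' @param envelope optional list `(xmin, xmax, ymin, ymax)`; defaults to the
#'   records' coordinate envelope. A lattice outside the envelope triggers a
#'   warning and is flagged as extrapolation in the metadata.
#' @param out_dir optional directory for `.asc` output.
#' @param seed provenance seed recorded in the metadata.
#' @return list with `layers` (list of `m x n` matrices, north row first),
#'   `depth_centers`, `cellsize`, `meta`, and `files` if written.
#' @export
predict_map <- function(checkpoint, records, m = 12L, n = 9L,
                        depth_edges = seq(0, 6, by = 0.5),
                        envelope = NULL, out_dir = NULL, seed = NA_integer_) {
  ck <- if (is.character(checkpoint) || inherits(checkpoint, "interp3d_checkpoint"))
    load_checkpoint(checkpoint) else checkpoint
  net <- ck$network; norm <- ck$normalization
  records <- as_borehole_records(records)
  env <- envelope %||% list(xmin = min(records$easting),
                            xmax = max(records$easting),
                            ymin = min(records$northing),
                            ymax = max(records$northing))
  extrapolating <- !is.null(envelope) &&
    (env$xmin < min(records$easting) || env$xmax > max(records$easting) ||
     env$ymin < min(records$northing) || env$ymax > max(records$northing))
  if (extrapolating)
    warning("query lattice extends beyond the sampled coordinate envelope; ",
            "predictions there are extrapolation")
  eastings <- seq(env$xmin, env$xmax, length.out = n)
  northings <- seq(env$ymax, env$ymin, length.out = m)
  cellsize <- if (n > 1) (env$xmax - env$xmin) / (n - 1) else 1
  D <- length(depth_edges) - 1L
  depth_centers <- (depth_edges[-1] + depth_edges[-length(depth_edges)]) / 2

  lattice <- expand.grid(d = seq_len(D), r = seq_len(m), c = seq_len(n))
  qx <- eastings[lattice$c]; qy <- northings[lattice$r]
  qz <- depth_centers[lattice$d]
  cov_cols <- borehole_features()[-(1:3)]
  covm <- idw_predict(cbind(records$easting, records$northing, records$depth,
                            as.matrix(records[cov_cols])),
                      cbind(qx, qy, qz), power = 2)
  channels <- borehole_features()
  feats <- array(NA_real_, dim = c(D, m, n, length(channels)))
  feats[, , , 1] <- qx; feats[, , , 2] <- qy; feats[, , , 3] <- qz
  for (j in seq_along(cov_cols)) feats[, , , 3 + j] <- covm[, j]
  for (ci in seq_along(channels))
    feats[, , , ci] <- apply_normalization(feats[, , , ci],
                                           norm[[channels[ci]]])
  pred <- forward(net, feats)
  pred_orig <- invert_normalization(pred, norm[["tph"]])
  layers <- lapply(seq_len(D), function(d)
    matrix(pred_orig[d, , ], m, n))
  meta <- list(seed = seed, format_version = CHECKPOINT_FORMAT_VERSION,
               package_version = as.character(utils::packageVersion("petromap3d")),
               fingerprint = config_fingerprint(unclass(net$cfg)),
               extrapolation = extrapolating,
               cellsize = cellsize, depth_edges = depth_edges)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(seq_len(D), function(d) {
      path <- file.path(out_dir, sprintf("tph_layer_%02d.asc", d))
      write_esri_ascii(layers[[d]], path,
                       xllcorner = env$xmin - cellsize / 2,
                       yllcorner = env$ymin - cellsize / 2,
                       cellsize = cellsize)
      path
    }, character(1))
    jsonlite::write_json(meta, file.path(out_dir, "map_meta.json"),
                         auto_unbox = TRUE)
  }
  list(layers = layers, depth_centers = depth_centers, cellsize = cellsize,
       meta = meta, files = files)
}
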
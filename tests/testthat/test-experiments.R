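test_that("the benchmark produces one row set per method and rejects unknowns", {
  ds <- scenario_dataset("paperlike", seed = 1)
  tc <- train_config(epochs = 15)
  res <- run_benchmark(ds$grid, ds$split,
                       methods = c("kriging3d", "idw", "cnn3d_cam"),
                       seeds = 1, train_cfg = tc)
  expect_setequal(unique(res$reports$method), c("kriging3d", "idw", "cnn3d_cam"))
  expect_setequal(unique(res$reports$split), c("validation", "test"))
  expect_equal(nrow(res$summary), 3L)
  expect_true(all(nchar(res$reports$fingerprint) > 0))
  expect_error(run_benchmark(ds$grid, ds$split, methods = "svm9000"),
               "unknown method")
})

test_that("a perfect oracle adapter tops the benchmark with r2 = 1", {
  ds <- scenario_dataset("paperlike", seed = 2)
  # leak the truth intentionally: features row -> target via the grid
  oracle <- function(grid, cells) grid$target[petromap3d:::cells_lin(grid, cells)]
  rep <- evaluate(oracle, ds$grid, ds$split, "test", method = "oracle")
  expect_equal(rep$r2, 1)
})

test_that("ablation variants differ by exactly the ablated element", {
  base <- model_config(seed = 9)
  cam_off <- petromap3d:::cnn_variant_config("cnn3d", base)
  diffs <- names(which(!mapply(identical, unclass(base), unclass(cam_off))))
  expect_equal(diffs, "use_cam")
  flat <- petromap3d:::cnn_variant_config("cnn2d", base)
  expect_true(flat$collapse_depth)
  expect_false(flat$use_cam)
  expect_true(all(sapply(flat$encoder_kernels, function(k) k[1] == 1L)))
})

test_that("feature ablation retrains reproducibly and reports every row", {
  ds <- scenario_dataset("linear_oracle", seed = 3)
  tc <- train_config(epochs = 15)
  res <- run_feature_ablation(ds$grid, ds$split,
                              features = c("organic", "ph"),
                              seeds = 3, train_cfg = tc)
  expect_setequal(res$summary$dropped, c("all", "organic", "ph"))
  # dropping then re-adding a feature reproduces the reference run exactly
  res2 <- run_feature_ablation(ds$grid, ds$split, features = "ph",
                               seeds = 3, train_cfg = tc)
  all1 <- res$reports[res$reports$dropped == "all", c("rmse", "r2", "mae")]
  all2 <- res2$reports[res2$reports$dropped == "all", c("rmse", "r2", "mae")]
  expect_equal(all1, all2)
  expect_error(run_feature_ablation(ds$grid, ds$split, features = "bogus",
                                    seeds = 1), "unknown")
})

test_that("dense maps agree with forward outputs on the training lattice", {
  ds <- scenario_dataset("paperlike", seed = 4)
  net <- build_interpolator(model_config(seed = 4), dim(ds$grid$features))
  fit <- train(net, ds$grid, ds$split, train_config(epochs = 10, seed = 4))
  ck <- save_checkpoint(fit$network, ds$norm)
  rec <- ds$grid$records
  mp <- predict_map(ck, rec, m = 4, n = 3,
                    depth_edges = ds$grid$depth_edges)
  fwd <- invert_normalization(forward(fit$network, ds$grid), ds$norm$tph)
  # identical lattice geometry and covariate imputation -> identical maps
  got <- simplify2array(mp$layers)          # (m, n, D)
  want <- aperm(fwd, c(2, 3, 1))
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("ESRI ASCII rasters carry the declared header geometry", {
  dir <- tempfile()
  m <- matrix(1:12 / 7, 3, 4)
  path <- file.path(tempdir(), "layer.asc")
  write_esri_ascii(m, path, xllcorner = 100, yllcorner = 200, cellsize = 17)
  lines <- readLines(path)
  expect_equal(lines[1], "ncols 4")
  expect_equal(lines[2], "nrows 3")
  expect_equal(lines[5], "cellsize 17")
  expect_equal(length(lines), 6 + 3)
})

test_that("map export writes one raster per depth layer plus metadata", {
  ds <- scenario_dataset("paperlike", seed = 5)
  net <- build_interpolator(model_config(seed = 5), dim(ds$grid$features))
  fit <- train(net, ds$grid, ds$split, train_config(epochs = 5, seed = 5))
  ck <- save_checkpoint(fit$network, ds$norm)
  out <- tempfile("maps")
  mp <- predict_map(ck, ds$grid$records, m = 6, n = 5,
                    depth_edges = c(0, 2, 4, 6), out_dir = out, seed = 5)
  expect_equal(length(mp$files), 3L)
  expect_true(all(file.exists(mp$files)))
  meta <- jsonlite::read_json(file.path(out, "map_meta.json"))
  expect_equal(meta$seed, 5L)
  expect_false(meta$extrapolation)
  expect_true(nchar(meta$fingerprint) > 0)
  # enlarged envelope flags extrapolation
  env <- list(xmin = min(ds$grid$records$easting) - 50,
              xmax = max(ds$grid$records$easting) + 50,
              ymin = min(ds$grid$records$northing) - 50,
              ymax = max(ds$grid$records$northing) + 50)
  expect_warning(predict_map(ck, ds$grid$records, m = 4, n = 3,
                             depth_edges = c(0, 2, 4, 6), envelope = env),
                 "extrapolation")
})

test_that("hotspot scenarios concentrate contamination in the right corner", {
  # the configured hotspot sits at the maximum-easting / minimum-northing
  # corner; its corner cells should carry more contamination than the
  # opposite corner in a typical realization
  ps <- scenario_params("paperlike")
  contrast <- sapply(1:6, function(s) {
    rec <- generate_field(ps, seed = s)
    ue <- sort(unique(rec$easting)); un <- sort(unique(rec$northing))
    hot <- rec$easting == max(ue) & rec$northing == min(un)
    cold <- rec$easting == min(ue) & rec$northing == max(un)
    mean(rec$tph[hot]) - mean(rec$tph[cold])
  })
  expect_gt(median(contrast), 0)
})
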
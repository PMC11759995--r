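test_that("empirical semivariogram bins pairs by 3D distance", {
  pts <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 2))
  emp <- empirical_variogram(pts, c(0, 2))
  expect_equal(emp$gamma, 2)          # (1/2) * (2 - 0)^2
  expect_equal(emp$npairs, 1L)

  set.seed(2)
  pts <- cbind(matrix(runif(30), 10, 3) * 10, 5)  # constant field
  emp <- empirical_variogram(pts, seq(0, 20, 2))
  expect_true(all(emp$gamma[emp$npairs > 0] == 0))
  expect_equal(sum(emp$npairs), 10 * 9 / 2)
  expect_error(empirical_variogram(pts, c(100, 200)), "outside")
})

test_that("variogram fitting recovers known parameters", {
  truth <- variogram_model("spherical", nugget = 0, sill = 1, range = 10)
  h <- seq(0.5, 15, by = 0.5)
  emp <- data.frame(dist = h, gamma = vgm_gamma(truth, h), npairs = 50L)
  fit <- fit_variogram(emp, "spherical")
  expect_lt(abs(fit$nugget - 0), 1e-3)
  expect_lt(abs(fit$sill - 1), 1e-3)
  expect_lt(abs(fit$range - 10), 1e-2)
})

test_that("doubling semivariances doubles nugget and sill but not range", {
  truth <- variogram_model("exponential", nugget = 0.2, sill = 1.2, range = 8)
  h <- seq(0.5, 20, by = 0.5)
  emp <- data.frame(dist = h, gamma = vgm_gamma(truth, h), npairs = 20L)
  f1 <- fit_variogram(emp, "exponential")
  emp2 <- emp; emp2$gamma <- 2 * emp2$gamma
  f2 <- fit_variogram(emp2, "exponential")
  expect_equal(f2$nugget, 2 * f1$nugget, tolerance = 1e-2)
  expect_equal(f2$sill, 2 * f1$sill, tolerance = 1e-2)
  expect_equal(f2$range, f1$range, tolerance = 1e-2)
})

test_that("degenerate empirical variograms fall back to pure nugget", {
  emp <- data.frame(dist = 1:5, gamma = 0, npairs = 10L)
  expect_warning(fit <- fit_variogram(emp, "spherical"), "nugget")
  expect_equal(fit$nugget, 0)
  expect_equal(fit$sill, 0)
})

test_that("ordinary kriging is exact at samples and unbiased everywhere", {
  set.seed(5)
  coords <- matrix(runif(60, 0, 50), 20, 3)
  vals <- sin(coords[, 1] / 10) + coords[, 3] / 50
  model <- variogram_model("spherical", nugget = 0, sill = 1, range = 30)
  ks <- kriging_fit(coords, vals, model)

  # exact interpolation with zero nugget
  at_samples <- kriging3d_predict(ks, coords[1:5, ])
  expect_lt(max(abs(at_samples$prediction - vals[1:5])), 1e-8)

  # weights sum to one on 100 random queries
  q <- matrix(runif(300, -10, 60), 100, 3)
  w <- kriging3d_predict(ks, q)$weights
  expect_lt(max(abs(colSums(w) - 1)), 1e-8)
})

test_that("two equidistant samples get symmetric kriging weights", {
  coords <- rbind(c(0, 0, 0), c(10, 0, 0))
  model <- variogram_model("exponential", nugget = 0, sill = 1, range = 10)
  ks <- kriging_fit(coords, c(1, 3), model)
  r <- kriging3d_predict(ks, rbind(c(5, 0, 0)))
  expect_equal(as.vector(r$weights), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(r$prediction, 2)
})

test_that("pure-nugget kriging equals the sample mean, matching brute force", {
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 5))
  vals <- c(1, 2, 6)
  model <- variogram_model("spherical", nugget = 0.7, sill = 0.7, range = 5)
  ks <- kriging_fit(coords, vals, model)
  r <- kriging3d_predict(ks, rbind(c(50, 50, 2)))
  expect_equal(as.vector(r$weights), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(r$prediction, mean(vals), tolerance = 1e-8)

  # independent brute-force solve of the 4x4 OK system
  gam <- function(h) ifelse(h == 0, 0, 0.7)
  A <- rbind(cbind(gam(as.matrix(dist(coords))), 1), c(1, 1, 1, 0))
  b <- c(gam(sqrt(colSums((t(coords) - c(50, 50, 2))^2))), 1)
  w_brute <- unname(solve(A, b)[1:3])
  expect_equal(as.vector(r$weights), w_brute, tolerance = 1e-8)
})

test_that("IDW reproduces hand-worked weights and stays bounded", {
  pts <- rbind(c(0, 0, 0, 0), c(0, 0, 3, 3))   # distances 1 and 2 from query
  expect_equal(idw_predict(pts, rbind(c(0, 0, 1)), power = 2), 0.6)
  # coincident query returns the sample value exactly
  expect_equal(idw_predict(pts, rbind(c(0, 0, 3))), 3)
  # equidistant samples: arithmetic mean for any power
  for (p in c(1, 2, 5))
    expect_equal(idw_predict(pts, rbind(c(0, 0, 1.5)), power = p), 1.5)
  set.seed(3)
  pts <- cbind(matrix(runif(45, 0, 10), 15, 3), rnorm(15))
  q <- matrix(runif(30, 0, 10), 10, 3)
  pred <- idw_predict(pts, q)
  expect_true(all(pred >= min(pts[, 4]) & pred <= max(pts[, 4])))
})

test_that("the feed-forward baseline learns a linear map and is seeded", {
  set.seed(10)
  X <- matrix(runif(200 * 9), 200, 9)
  y <- 0.2 + 0.5 * X[, 4]
  idx <- 1:140; vidx <- 141:170; tidx <- 171:200
  cfg <- train_config(epochs = 200, seed = 1)
  f1 <- fnn_baseline(X[idx, ], y[idx], X[vidx, ], y[vidx], cfg = cfg)
  expect_gt(r_squared(y[tidx], predict(f1, X[tidx, ])), 0.99)
  f2 <- fnn_baseline(X[idx, ], y[idx], X[vidx, ], y[vidx], cfg = cfg)
  expect_identical(predict(f1, X[tidx, ]), predict(f2, X[tidx, ]))
})

test_that("the feed-forward baseline finds no signal in shuffled targets", {
  set.seed(20)
  r2s <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(runif(120 * 5), 120, 5)
    y <- sample(0.2 + 0.5 * X[, 2])   # permuted: no relation to X
    f <- fnn_baseline(X[1:80, ], y[1:80], X[81:100, ], y[81:100],
                      hidden = c(16, 8),
                      cfg = train_config(epochs = 80, seed = s))
    r_squared(y[101:120], predict(f, X[101:120, ]))
  })
  expect_lte(median(r2s), 0.2)
})

test_that("external regressors join the benchmark through the adapter", {
  ds <- scenario_dataset("paperlike", seed = 11)
  mean_adapter <- external_regressor_adapter(
    "mean", fit = function(X, y) mean(y),
    predict = function(state, X) rep(state, nrow(X)))
  fitted <- fit_method("adapter", ds$grid, ds$split, adapter = mean_adapter)
  rep <- evaluate(fitted, ds$grid, ds$split, "test", method = "mean")
  expect_lte(rep$r2, 0)
  expect_equal(rep$n, nrow(ds$split$test))

  bad <- external_regressor_adapter(
    "bad", fit = function(X, y) NULL,
    predict = function(state, X) 1)
  fitted_bad <- fit_method("adapter", ds$grid, ds$split, adapter = bad)
  expect_error(predict_cells(fitted_bad, ds$grid, ds$split$test), "contract")
  expect_error(external_regressor_adapter("x", fit = 1, predict = identity),
               "contract")
})

test_that("an adapter wrapping the FNN matches the direct FNN evaluation", {
  ds <- scenario_dataset("linear_oracle", seed = 12)
  cfg <- train_config(epochs = 60, seed = 12)
  direct <- fit_method("fnn", ds$grid, ds$split, seed = 12, train_cfg = cfg)
  tr <- ds$split$train; va <- ds$split$validation
  Xv <- petromap3d:::cell_features(ds$grid, va)
  yv <- ds$grid$target[petromap3d:::cells_lin(ds$grid, va)]
  wrap <- external_regressor_adapter(
    "fnn_wrapped",
    fit = function(X, y) fnn_baseline(X, y, Xv, yv, cfg = cfg),
    predict = function(state, X) predict(state, X))
  wrapped <- fit_method("adapter", ds$grid, ds$split, adapter = wrap)
  r1 <- evaluate(direct, ds$grid, ds$split, "test", method = "fnn")
  r2 <- evaluate(wrapped, ds$grid, ds$split, "test", method = "fnn")
  expect_equal(r1[c("rmse", "r2", "mae", "n")], r2[c("rmse", "r2", "mae", "n")])
})

test_that("an external SVR joins the benchmark through the adapter", {
  skip_if_not_installed("e1071")
  ds <- scenario_dataset("paperlike", seed = 13)
  svr <- external_regressor_adapter(
    "svr",
    fit = function(X, y) e1071::svm(X, y),
    predict = function(state, X) as.numeric(predict(state, X)))
  res <- run_benchmark(ds$grid, ds$split, methods = "idw", seeds = 1,
                       adapters = list(svr = svr))
  expect_true("svr" %in% res$reports$method)
  expect_true(all(is.finite(res$reports$r2)))
})
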
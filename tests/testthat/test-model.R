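test_that("the direct convolution sum reproduces hand-worked cases", {
  x <- array(1, c(2, 2, 2, 1))
  k <- array(1, c(2, 2, 2, 1, 1))
  expect_equal(as.vector(conv3d_reference(x, k, 0, "relu")), 8)

  # Kronecker delta at the kernel origin passes the valid region through
  set.seed(1)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  k <- array(0, c(2, 2, 2, 2, 2))
  k[1, 1, 1, 1, 1] <- 1; k[1, 1, 1, 2, 2] <- 1
  out <- conv3d_reference(x, k, c(0, 0), "identity")
  expect_equal(out, x[1:3, 1:3, 1:3, , drop = FALSE])

  # all-negative pre-activations are clamped by ReLU
  x <- array(1, c(3, 3, 3, 1))
  k <- array(-1, c(2, 2, 2, 1, 1))
  expect_true(all(conv3d_reference(x, k, 0, "relu") == 0))

  expect_error(conv3d_reference(array(1, c(2, 2, 2, 1)),
                                array(1, c(3, 2, 2, 1, 1)), 0), "extents")
})

test_that("the GEMM convolution path matches the direct oracle", {
  set.seed(11)
  for (i in 1:10) {
    di <- c(sample(2:5, 3, replace = TRUE), sample(1:4, 1))
    dk <- c(pmin(sample(1:3, 3, replace = TRUE), di[1:3]), di[4], sample(1:4, 1))
    x <- array(rnorm(prod(di)), di)
    k <- array(rnorm(prod(dk)), dk)
    b <- rnorm(dk[5])
    got <- petromap3d:::conv3d_gemm(x, k, b, "relu")$out
    want <- conv3d_reference(x, k, b, "relu")
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("channel attention satisfies its pooling and scaling contracts", {
  C <- 4
  w <- petromap3d:::with_seed(2, cam_init(C, 2))
  # zero MLP -> sigmoid(0 + 0) = 0.5 for every channel
  w0 <- w; w0$W1[] <- 0; w0$W2[] <- 0
  fm <- array(rnorm(2 * 2 * 2 * C), c(2, 2, 2, C))
  r0 <- channel_attention(fm, w0)
  expect_equal(r0$mc, rep(0.5, C))
  expect_equal(r0$out, 0.5 * fm)

  # channel-constant input: max pool equals avg pool exactly
  fmc <- array(rep(c(1.5, -2, 0.25, 7), each = 8), c(2, 2, 2, C))
  cache <- channel_attention(fmc, w, keep_cache = TRUE)$cache
  expect_identical(cache$amax, cache$aavg)
})

test_that("channel attention matches an independent step-by-step evaluation", {
  set.seed(33)
  C <- 3
  fm <- array(rnorm(2 * 2 * 2 * C), c(2, 2, 2, C))
  w <- petromap3d:::with_seed(5, cam_init(C, 2))
  got <- channel_attention(fm, w)

  # hand evaluation: pool -> shared MLP on both -> add -> sigmoid -> scale
  fmm <- matrix(fm, 8, C)
  amax <- apply(fmm, 2, max); aavg <- colMeans(fmm)
  mlp <- function(a) as.vector(w$W2 %*% pmax(w$W1 %*% a + w$b1, 0) + w$b2)
  mc <- 1 / (1 + exp(-(mlp(amax) + mlp(aavg))))
  scaled <- array(fmm * rep(mc, each = 8), dim = dim(fm))
  expect_lt(max(abs(got$mc - mc)), 1e-6)
  expect_lt(max(abs(got$out - scaled)), 1e-6)
  expect_true(all(got$mc > 0 & got$mc < 1))
})

test_that("each output channel is exactly linear in its attention weight", {
  set.seed(14)
  C <- 5
  fm <- array(rnorm(3 * 2 * 2 * C), c(3, 2, 2, C))
  w <- petromap3d:::with_seed(6, cam_init(C, 2))
  r <- channel_attention(fm, w)
  for (ci in seq_len(C))
    expect_equal(r$out[, , , ci], fm[, , , ci] * r$mc[ci])
})

test_that("builder restores the input spatial shape for the default config", {
  net <- build_interpolator(model_config(), c(3, 4, 3, 9))
  x <- array(runif(3 * 4 * 3 * 9), c(3, 4, 3, 9))
  expect_equal(dim(forward(net, x)), c(3, 4, 3))
  # the same architecture generalizes to deeper grids
  net12 <- build_interpolator(model_config(), c(12, 4, 3, 9))
  x12 <- array(runif(12 * 4 * 3 * 9), c(12, 4, 3, 9))
  expect_equal(dim(forward(net12, x12)), c(12, 4, 3))
})

test_that("builder rejects unsolvable or ill-fitting configurations", {
  # kernel larger than the feature map
  expect_error(build_interpolator(
    model_config(encoder_kernels = list(c(5, 2, 2), c(2, 2, 2), c(1, 2, 1))),
    c(3, 4, 3, 9)), "configuration error")
  # fully specified decoder that does not restore the input shape
  expect_error(build_interpolator(
    model_config(decoder_kernels = list(c(1, 2, 1), c(1, 2, 2), c(1, 1, 1))),
    c(3, 4, 3, 9)), "configuration error")
})

test_that("disabling attention yields identity blocks, not different weights", {
  cfg_on <- tiny_model_cfg(seed = 4)
  cfg_off <- tiny_model_cfg(seed = 4, use_cam = FALSE)
  x <- array(runif(3 * 4 * 3 * 9), c(3, 4, 3, 9))
  net_off <- build_interpolator(cfg_off, c(3, 4, 3, 9))
  # a CAM net whose attention output is forced to 1 equals the CAM-free net
  net_on <- build_interpolator(cfg_on, c(3, 4, 3, 9))
  for (li in seq_along(net_on$layers))
    if (net_on$layers[[li]]$type == "cam") net_on$layers[[li]]$identity <- TRUE
  expect_equal(forward(net_on, x), forward(net_off, x))
})

test_that("building and inference are deterministic in the seed", {
  x <- array(runif(3 * 4 * 3 * 9), c(3, 4, 3, 9))
  n1 <- build_interpolator(model_config(seed = 21), c(3, 4, 3, 9))
  n2 <- build_interpolator(model_config(seed = 21), c(3, 4, 3, 9))
  expect_identical(forward(n1, x), forward(n2, x))
  expect_identical(forward(n1, x), forward(n1, x))
  n3 <- build_interpolator(model_config(seed = 22), c(3, 4, 3, 9))
  expect_false(identical(forward(n1, x), forward(n3, x)))
})

test_that("backpropagation matches finite differences", {
  # smooth activations throughout: finite differences are invalid at the
  # kinks of piecewise-linear activations
  cfg <- tiny_model_cfg(seed = 3, conv_inner_activation = "tanh",
                        mlp_activation = "tanh")
  net <- build_interpolator(cfg, c(3, 4, 3, 5))
  set.seed(8)
  x <- array(runif(3 * 4 * 3 * 5), c(3, 4, 3, 5))
  tgt <- array(runif(3 * 4 * 3), c(3, 4, 3))
  lin <- 1:30
  loss_fn <- function(net) {
    p <- petromap3d:::net_forward(net, x)
    mean((p[lin] - tgt[lin])^2)
  }
  fw <- petromap3d:::net_forward(net, x, keep_cache = TRUE)
  dP <- array(0, dim(fw$out)); dP[lin] <- 2 * (fw$out[lin] - tgt[lin]) / 30
  grads <- petromap3d:::grads_as_params(
    net, petromap3d:::net_backward(net, fw$caches, dP))
  params <- petromap3d:::net_params(net)
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- loss_fn(petromap3d:::net_set_params(net, p2))
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- loss_fn(petromap3d:::net_set_params(net, p2))
      fd <- (l1 - l0) / (2 * eps)
      expect_lt(abs(fd - grads[[nm]][i]),
                1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("checkpoints round-trip forward outputs bit-for-bit", {
  ds <- scenario_dataset("paperlike", seed = 9)
  net <- build_interpolator(model_config(seed = 9), dim(ds$grid$features))
  fit <- train(net, ds$grid, ds$split, train_config(epochs = 5, seed = 9))
  path <- withr_tempfile(fileext = ".json")
  save_checkpoint(fit$network, ds$norm, path)
  back <- load_checkpoint(path)
  expect_identical(forward(back$network, ds$grid), forward(fit$network, ds$grid))
  # normalization params travel with the checkpoint
  expect_equal(back$normalization$tph, ds$norm$tph)
})

test_that("corrupt or unversioned checkpoints fail loudly", {
  ds <- scenario_dataset("paperlike", seed = 9)
  net <- build_interpolator(model_config(seed = 9), dim(ds$grid$features))
  ck <- save_checkpoint(net, ds$norm)
  ck$format_version <- 99L
  expect_error(load_checkpoint(ck), "version")
  ck2 <- save_checkpoint(net, ds$norm)
  ck2$weights[[1]]$data <- ck2$weights[[1]]$data[1:3]
  expect_error(load_checkpoint(ck2), "truncated")
})
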
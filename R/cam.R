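# Channel attention (squeeze-excite style): the feature map is pooled over
# all spatial positions by global max and global average pooling, both pooled
# vectors pass through one shared two-layer MLP, the two outputs are added and
# a sigmoid yields per-channel weights in (0,1) that rescale the map.

#' Initialize channel-attention MLP weights
#'
#' The shared MLP bottlenecks C channels to `max(1, floor(C / ratio))` hidden
#' units. Weights are drawn from the current RNG stream (Glorot-uniform).
#'
#' @param C number of channels.
#' @param reduction_ratio bottleneck divisor (default 2; channel counts in
#'   this model are small, so the common ratio 16 would collapse 16 channels
#'   to a single hidden unit).
#' @param mlp_activation hidden activation name.
#' @return list of MLP parameters `W1, b1, W2, b2` plus settings.
#' @export
cam_init <- function(C, reduction_ratio = 2, mlp_activation = "relu") {
  hidden <- max(1L, C %/% reduction_ratio)
  lim1 <- sqrt(6 / (C + hidden)); lim2 <- sqrt(6 / (hidden + C))
  list(W1 = matrix(stats::runif(hidden * C, -lim1, lim1), hidden, C),
       b1 = numeric(hidden),
       W2 = matrix(stats::runif(C * hidden, -lim2, lim2), C, hidden),
       b2 = numeric(C),
       mlp_activation = mlp_activation)
}

#' Apply channel attention to a feature map
#'
#' @param feature_map numeric array `(D, H, W, C)`.
#' @param weights MLP parameters from [cam_init()].
#' @param keep_cache internal: retain intermediates for backpropagation.
#' @return list with `out` (rescaled map), `mc` (per-channel attention
#'   weights in (0,1)), and optionally `cache`.
#' @export
channel_attention <- function(feature_map, weights, keep_cache = FALSE) {
  dm <- dim(feature_map)
  C <- dm[4]; nsp <- prod(dm[1:3])
  fm <- matrix(feature_map, nsp, C)
  amax_pos <- max.col(t(fm), ties.method = "first")   # argmax per channel
  amax <- fm[cbind(amax_pos, seq_len(C))]
  aavg <- colMeans(fm)
  mlp1 <- function(a) {
    pre <- as.vector(weights$W1 %*% a + weights$b1)
    list(pre = pre, h = act_apply(pre, weights$mlp_activation))
  }
  hm <- mlp1(amax); ha <- mlp1(aavg)
  om <- as.vector(weights$W2 %*% hm$h + weights$b2)
  oa <- as.vector(weights$W2 %*% ha$h + weights$b2)
  logit <- om + oa
  mc <- 1 / (1 + exp(-logit))
  out <- array(fm * rep(mc, each = nsp), dim = dm)
  res <- list(out = out, mc = mc)
  if (keep_cache)
    res$cache <- list(fm = fm, dm = dm, amax = amax, aavg = aavg,
                      amax_pos = amax_pos, hm = hm, ha = ha, mc = mc,
                      nsp = nsp)
  res
}

cam_backward <- function(dOut, cache, weights) {
  dm <- cache$dm; C <- dm[4]; nsp <- cache$nsp
  dOm <- matrix(dOut, nsp, C)
  dX <- dOm * rep(cache$mc, each = nsp)
  dmc <- colSums(cache$fm * dOm)
  dlogit <- dmc * cache$mc * (1 - cache$mc)
  dW1 <- matrix(0, nrow(weights$W1), ncol(weights$W1)); db1 <- numeric(nrow(weights$W1))
  dW2 <- matrix(0, nrow(weights$W2), ncol(weights$W2)); db2 <- numeric(C)
  branch <- function(hcache, a) {
    dW2 <<- dW2 + outer(dlogit, hcache$h)
    db2 <<- db2 + dlogit
    dh <- as.vector(crossprod(weights$W2, dlogit))
    dpre <- dh * act_grad(hcache$pre, weights$mlp_activation)
    dW1 <<- dW1 + outer(dpre, a)
    db1 <<- db1 + dpre
    as.vector(crossprod(weights$W1, dpre))   # da
  }
  da_max <- branch(cache$hm, cache$amax)
  da_avg <- branch(cache$ha, cache$aavg)
  # average pool spreads gradient uniformly; max pool routes it to the argmax
  dX <- dX + matrix(rep(da_avg / nsp, each = nsp), nsp, C)
  dX[cbind(cache$amax_pos, seq_len(C))] <-
    dX[cbind(cache$amax_pos, seq_len(C))] + da_max
  list(dX = array(dX, dim = dm), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}
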
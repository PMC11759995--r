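# Activation functions used across the network. Pre-activations are cached so
# gradients can be formed without re-computing forward passes.

act_apply <- function(x, name) {
  switch(name,
    relu     = pmax(x, 0),
    tanh     = tanh(x),
    sigmoid  = 1 / (1 + exp(-x)),
    identity = x,
    stop("unknown activation: ", name)
  )
}

act_grad <- function(pre, name) {
  switch(name,
    relu     = (pre > 0) * 1,
    tanh     = 1 - tanh(pre)^2,
    sigmoid  = { s <- 1 / (1 + exp(-pre)); s * (1 - s) },
    identity = array(1, dim = dim(pre) %||% length(pre)),
    stop("unknown activation: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direct evaluation of a 3D valid convolution
#'
#' Brute-force evaluation of the 3D convolution sum: for every output position
#' the kernel is laid over the input, products are summed over the three
#' kernel extents and all input channels, the bias is added, and the
#' activation applied. Stride 1, no padding ("valid"). This routine is the
#' independent oracle against which the fast GEMM-based layers are tested; it
#' deliberately shares no code with them.
#'
#' @param input numeric array `(D, H, W, C_in)`.
#' @param kernel numeric array `(kd, kh, kw, C_in, C_out)`.
#' @param bias numeric vector of length `C_out`.
#' @param activation one of `"relu"`, `"tanh"`, `"sigmoid"`, `"identity"`.
#' @return numeric array `(D-kd+1, H-kh+1, W-kw+1, C_out)`.
#' @export
conv3d_reference <- function(input, kernel, bias, activation = "relu") {
  di <- dim(input); dk <- dim(kernel)
  if (length(di) != 4L || length(dk) != 5L)
    stop("conv3d_reference: input must be rank-4 and kernel rank-5")
  if (di[4] != dk[4])
    stop("conv3d_reference: input channels (", di[4], ") != kernel channels (", dk[4], ")")
  if (any(dk[1:3] > di[1:3]))
    stop("conv3d_reference: kernel extents ", paste(dk[1:3], collapse = "x"),
         " exceed input extents ", paste(di[1:3], collapse = "x"))
  Do <- di[1] - dk[1] + 1L; Ho <- di[2] - dk[2] + 1L; Wo <- di[3] - dk[3] + 1L
  Cout <- dk[5]
  out <- array(0, dim = c(Do, Ho, Wo, Cout))
  for (j in seq_len(Cout)) {
    for (d in seq_len(Do)) for (h in seq_len(Ho)) for (w in seq_len(Wo)) {
      acc <- bias[j]
      for (x in seq_len(dk[1])) for (y in seq_len(dk[2])) for (z in seq_len(dk[3]))
        for (k in seq_len(dk[4]))
          acc <- acc + kernel[x, y, z, k, j] * input[d + x - 1L, h + y - 1L, w + z - 1L, k]
      out[d, h, w, j] <- acc
    }
  }
  act_apply(out, activation)
}

# -- GEMM (im2col) convolution ------------------------------------------------
# The fast path used by the network. Patch-extraction indices depend only on
# the input/kernel shapes, so they are computed once per layer and cached.

im2col_indices <- function(in_shape, kernel_shape) {
  D <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]; C <- in_shape[4]
  kd <- kernel_shape[1]; kh <- kernel_shape[2]; kw <- kernel_shape[3]
  if (any(kernel_shape[1:3] > in_shape[1:3]))
    stop("kernel extents ", paste(kernel_shape[1:3], collapse = "x"),
         " exceed input extents ", paste(in_shape[1:3], collapse = "x"))
  Do <- D - kd + 1L; Ho <- H - kh + 1L; Wo <- W - kw + 1L
  pos <- expand.grid(d = seq_len(Do), h = seq_len(Ho), w = seq_len(Wo))
  off <- expand.grid(x = 0:(kd - 1L), y = 0:(kh - 1L), z = 0:(kw - 1L),
                     c = seq_len(C))
  # linear index of (d,h,w,c) in a (D,H,W,C) array, column-major
  idx <- outer(pos$d, off$x, `+`) +
    (outer(pos$h, off$y, `+`) - 1L) * D +
    (outer(pos$w, off$z, `+`) - 1L) * (D * H) +
    matrix((off$c - 1L) * (D * H * W), nrow(pos), nrow(off), byrow = TRUE)
  list(idx = idx, out_spatial = c(Do, Ho, Wo), in_shape = in_shape,
       kernel_shape = kernel_shape)
}

conv3d_gemm <- function(input, W, b, activation = "relu", im2col = NULL) {
  dk <- dim(W)
  if (is.null(im2col) || !all(dim(input) == im2col$in_shape))
    im2col <- im2col_indices(dim(input), dk)
  # index with a plain vector: a matrix subscript whose column count equals
  # the array rank would be treated as coordinate indexing
  P <- matrix(input[as.vector(im2col$idx)], nrow = nrow(im2col$idx))
  Wmat <- matrix(W, nrow = prod(dk[1:4]), ncol = dk[5])
  pre <- P %*% Wmat
  pre <- sweep(pre, 2L, b, `+`)
  outdim <- c(im2col$out_spatial, dk[5])
  out <- array(act_apply(pre, activation), dim = outdim)
  list(out = out,
       cache = list(P = P, pre = pre, im2col = im2col, Wmat = Wmat,
                    activation = activation, kdim = dk))
}

conv3d_gemm_backward <- function(dOut, cache) {
  npos <- nrow(cache$P)
  Cout <- cache$kdim[5]
  dOutm <- matrix(dOut, nrow = npos, ncol = Cout)
  dPre <- dOutm * matrix(act_grad(cache$pre, cache$activation), npos, Cout)
  dW <- array(crossprod(cache$P, dPre), dim = cache$kdim)
  db <- colSums(dPre)
  dP <- dPre %*% t(cache$Wmat)
  dX <- array(0, dim = cache$im2col$in_shape)
  idx <- cache$im2col$idx
  # input positions within one column are distinct for stride-1 valid conv,
  # so per-column accumulation is collision-free
  for (j in seq_len(ncol(idx)))
    dX[idx[, j]] <- dX[idx[, j]] + dP[, j]
  list(dX = dX, dW = dW, db = db)
}

# -- Transposed 3D convolution ------------------------------------------------
# Realized as a valid convolution of the zero-padded input with the spatially
# flipped kernel; output extent is input + kernel - 1 per axis.

flip_kernel <- function(W) {
  dk <- dim(W)
  W[rev(seq_len(dk[1])), rev(seq_len(dk[2])), rev(seq_len(dk[3])), , , drop = FALSE]
}

pad_input <- function(x, pad) {
  dx <- dim(x)
  out <- array(0, dim = c(dx[1] + 2L * pad[1], dx[2] + 2L * pad[2],
                          dx[3] + 2L * pad[3], dx[4]))
  out[pad[1] + seq_len(dx[1]), pad[2] + seq_len(dx[2]),
      pad[3] + seq_len(dx[3]), ] <- x
  out
}

tconv3d <- function(input, W, b, activation = "tanh", im2col = NULL) {
  dk <- dim(W)
  pad <- dk[1:3] - 1L
  xp <- pad_input(input, pad)
  res <- conv3d_gemm(xp, flip_kernel(W), b, activation, im2col = im2col)
  res$cache$pad <- pad
  res$cache$in_dim <- dim(input)
  res
}

tconv3d_backward <- function(dOut, cache) {
  g <- conv3d_gemm_backward(dOut, cache)
  pad <- cache$pad; din <- cache$in_dim
  dX <- g$dX[pad[1] + seq_len(din[1]), pad[2] + seq_len(din[2]),
             pad[3] + seq_len(din[3]), , drop = FALSE]
  list(dX = dX, dW = flip_kernel(g$dW), db = g$db)
}

# -- batch normalization ------------------------------------------------------
# The model trains on a single full-batch grid tensor, so normalization
# statistics are per channel over all spatial positions. Training uses batch
# statistics and maintains exponential running statistics for inference.

bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       train = FALSE, momentum = 0.1, eps = 1e-5) {
  dm <- dim(x); C <- dm[4]; nsp <- prod(dm[1:3])
  xm <- matrix(x, nsp, C)
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    new_rm <- (1 - momentum) * running_mean + momentum * mu
    new_rv <- (1 - momentum) * running_var + momentum * va
  } else {
    mu <- running_mean; va <- running_var
    new_rm <- running_mean; new_rv <- running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = nsp)) * rep(inv_sd, each = nsp)
  y <- xhat * rep(gamma, each = nsp) + rep(beta, each = nsp)
  list(out = array(y, dim = dm),
       cache = list(xm = xm, xhat = xhat, mu = mu, inv_sd = inv_sd,
                    gamma = gamma, dm = dm, nsp = nsp, train = train),
       running_mean = new_rm, running_var = new_rv)
}

bn_backward <- function(dOut, cache) {
  dm <- cache$dm; C <- dm[4]; nsp <- cache$nsp
  dy <- matrix(dOut, nsp, C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(cache$gamma, each = nsp)
  if (cache$train) {
    # batch statistics were functions of x
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - rep(s1 / nsp, each = nsp) -
             cache$xhat * rep(s2 / nsp, each = nsp)) *
      rep(cache$inv_sd, each = nsp)
  } else {
    dx <- dxhat * rep(cache$inv_sd, each = nsp)
  }
  list(dX = array(dx, dim = dm), dgamma = dgamma, dbeta = dbeta)
}

# Evaluate a scoped expression with a temporary RNG seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
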
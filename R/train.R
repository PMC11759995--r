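# Training: full-batch Adam on masked mean-squared error, with
# reduce-on-plateau learning-rate decay (x 1/10 when validation loss stops
# improving) and seeded reproducibility. The network is trained on the single
# (D, m, n, T) grid tensor; the train/validation partitions select which
# cells contribute to each loss.

#' Training configuration
#'
#' @param epochs number of epochs (no early stopping).
#' @param learning_rate initial Adam learning rate.
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate is reduced.
#' @param plateau_factor multiplicative reduction factor (default 0.1).
#' @param min_lr learning-rate floor; defaults to one tenth of the initial
#'   rate, so plateau decay performs exactly one order-of-magnitude step
#'   ("the rate decreases to 1/10 of its original value") and full-batch
#'   optimization — one update per epoch — is never frozen outright.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param seed integer seed for dropout and any other training randomness.
#' @param full_batch kept for provenance; the loop always performs one update
#'   per epoch over all training cells.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 400L, learning_rate = 0.01,
                         plateau_patience = 10L, plateau_factor = 0.1,
                         min_lr = learning_rate / 10, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1L, full_batch = TRUE) {
  if (plateau_factor <= 0 || plateau_factor >= 1)
    stop("plateau_factor must lie in (0, 1)")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, min_lr = min_lr,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed), full_batch = isTRUE(full_batch)),
            class = "train_config")
}

#' Masked mean squared error
#'
#' Mean of squared prediction errors over mask-true cells only; sentinel
#' values in masked-out cells can never leak into the loss.
#'
#' @param pred,target numeric arrays of equal shape.
#' @param mask logical array of the same shape with at least one `TRUE` cell.
#' @export
mse_loss <- function(pred, target, mask) {
  if (!all(dim(pred) == dim(target)) || !all(dim(pred) == dim(mask)))
    stop("pred, target and mask must have identical shapes")
  idx <- which(mask)
  if (!length(idx)) stop("mask has no TRUE cells")
  mean((pred[idx] - target[idx])^2)
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Walks a validation-loss history from the start: an epoch improves when its
#' loss is strictly below the best seen so far (by more than 1e-12); after
#' `patience` consecutive non-improving epochs the rate is multiplied by
#' `factor` (floored at `min_lr`) and the wait counter resets.
#'
#' @param history numeric vector of validation losses, oldest first.
#' @param patience consecutive non-improving epochs tolerated.
#' @param factor multiplicative reduction (e.g. 0.1 for "decay to 1/10").
#' @param current_lr learning rate before the history is applied.
#' @param min_lr floor.
#' @return the learning rate after processing the whole history.
#' @export
plateau_schedule <- function(history, patience, factor, current_lr,
                             min_lr = 0) {
  if (factor <= 0 || factor >= 1) stop("factor must lie in (0, 1)")
  lr <- current_lr
  best <- Inf; wait <- 0L
  for (loss in history) {
    if (loss < best - 1e-12) { best <- loss; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= patience) { lr <- max(lr * factor, min_lr); wait <- 0L }
    }
  }
  lr
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t; bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$epsilon)
  }
  list(params = params, state = state)
}

#' Train the interpolation network on a sample grid
#'
#' Full-batch Adam for exactly `cfg$epochs` epochs. The training loss is the
#' masked MSE over train cells; after every update the validation loss is
#' computed in inference mode (dropout off) and drives the plateau schedule.
#' The weights at the minimum validation loss are retained and returned.
#'
#' @param network an `interp3d_network`.
#' @param grid a normalized `sample_grid`.
#' @param split a `dataset_split` with nonempty train and validation sets.
#' @param cfg a [train_config()].
#' @return list with `network` (best-validation weights) and `history`
#'   (data frame: epoch, train_loss, val_loss, lr).
#' @export
train <- function(network, grid, split, cfg = train_config()) {
  stopifnot(inherits(network, "interp3d_network"),
            inherits(grid, "sample_grid"), inherits(split, "dataset_split"))
  if (is.null(grid$features)) stop("grid is not normalized")
  if (!nrow(split$train) || !nrow(split$validation))
    stop("train and validation partitions must be nonempty")
  x <- grid$features
  target <- grid$target
  dims <- dim(target)
  tr_lin <- cells_lin(grid, split$train)
  va_lin <- cells_lin(grid, split$validation)
  ntr <- length(tr_lin)

  params <- net_params(network)
  state <- adam_init(params)
  lr <- cfg$learning_rate
  best_val <- Inf; wait <- 0L
  best_params <- params
  best_bn <- get_bn_stats(network)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      fw <- net_forward(network, x, train = TRUE, keep_cache = TRUE)
      for (li in seq_along(network$layers))
        if (network$layers[[li]]$type == "bn") {
          network$layers[[li]]$running_mean <- fw$caches[[li]]$new_rm
          network$layers[[li]]$running_var <- fw$caches[[li]]$new_rv
        }
      pred <- fw$out
      resid <- pred[tr_lin] - target[tr_lin]
      train_loss <- mean(resid^2)
      if (!is.finite(train_loss))
        stop("non-finite training loss at epoch ", epoch,
             " (learning rate ", lr, ")")
      dPred <- array(0, dim = dim(pred))
      dPred[tr_lin] <- 2 * resid / ntr
      grads <- grads_as_params(network, net_backward(network, fw$caches, dPred))
      upd <- adam_step(params, grads, state, lr, cfg)
      params <- upd$params; state <- upd$state
      network <- net_set_params(network, params)

      val_pred <- net_forward(network, x, train = FALSE)
      val_loss <- mean((val_pred[va_lin] - target[va_lin])^2)
      if (!is.finite(val_loss))
        stop("non-finite validation loss at epoch ", epoch)
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; wait <- 0L
        best_params <- params
        best_bn <- get_bn_stats(network)
      } else {
        wait <- wait + 1L
        if (wait >= cfg$plateau_patience) {
          lr <- max(lr * cfg$plateau_factor, cfg$min_lr)
          wait <- 0L
        }
      }
      hist[epoch, ] <- list(epoch, train_loss, val_loss, lr)
    }
  })
  network <- net_set_params(network, best_params)
  network <- set_bn_stats(network, best_bn)
  list(network = network, history = hist)
}

#' Random hyperparameter search
#'
#' Draws `k` configurations uniformly (with replacement) from the candidate
#' sets, trains each, and scores it by validation-set R-squared. Ties are
#' broken by lower validation MAE, then draw order.
#'
#' @param space named list of candidate sets; recognized names:
#'   `learning_rate` (numeric vector) and `encoder_filters` (list of integer
#'   vectors).
#' @param k number of draws.
#' @param grid,split as in [train()].
#' @param seed seed for the draws (training seeds derive from it).
#' @param model_cfg,train_cfg base configurations the draws override.
#' @return list with `best` (list of `model_cfg`, `train_cfg`) and `table`
#'   (score table sorted by descending R-squared).
#' @export
random_search <- function(space, k, grid, split, seed = 1L,
                          model_cfg = model_config(),
                          train_cfg = train_config()) {
  if (k < 1L) stop("k must be >= 1")
  draws <- with_seed(seed, lapply(seq_len(k), function(i)
    lapply(space, function(cand)
      if (is.list(cand)) cand[[sample.int(length(cand), 1L)]]
      else cand[sample.int(length(cand), 1L)])))
  rows <- vector("list", k)
  configs <- vector("list", k)
  for (i in seq_len(k)) {
    mc <- model_cfg; tc <- train_cfg
    if (!is.null(draws[[i]]$learning_rate))
      tc$learning_rate <- draws[[i]]$learning_rate
    if (!is.null(draws[[i]]$encoder_filters)) {
      mc$encoder_filters <- as.integer(draws[[i]]$encoder_filters)
      if (length(mc$encoder_filters) != length(mc$encoder_kernels))
        stop("candidate encoder_filters length must match encoder_kernels")
    }
    res <- tryCatch({
      net <- build_interpolator(mc, dim(grid$features))
      fit <- train(net, grid, split, tc)
      pred <- forward(fit$network, grid)
      va <- cells_lin(grid, split$validation)
      list(r2 = r_squared(grid$target[va], pred[va]),
           mae = mae(grid$target[va], pred[va]))
    }, error = function(e) list(r2 = -Inf, mae = Inf))
    configs[[i]] <- list(model_cfg = mc, train_cfg = tc)
    rows[[i]] <- data.frame(
      draw = i,
      learning_rate = tc$learning_rate,
      encoder_filters = paste(mc$encoder_filters, collapse = "-"),
      r2 = res$r2, mae = res$mae)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r2, tab$mae, tab$draw)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = configs[[tab$draw[1]]], table = tab)
}
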
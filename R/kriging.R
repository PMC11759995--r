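# Ordinary kriging in three dimensions, built from first principles:
# empirical semivariogram over 3D Euclidean pair distances, weighted
# least-squares fit of a bounded variogram model (spherical / exponential /
# gaussian), and the ordinary-kriging linear system in semivariance form with
# a Lagrange multiplier enforcing the sum-to-one (unbiasedness) constraint.

#' Construct a variogram model
#'
#' Convention: `gamma(0) = 0`; the nugget applies in the limit `h -> 0+`;
#' `gamma(h)` rises monotonically to the sill. `range` is the practical
#' range (distance at which ~the sill is reached) for all three families.
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget nonnegative nugget variance.
#' @param sill total sill (`>= nugget`).
#' @param range practical range (`> 0`).
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget = 0, sill = 1, range = 1) {
  family <- match.arg(family)
  if (nugget < 0 || sill < nugget || range <= 0)
    stop("need nugget >= 0, sill >= nugget, range > 0")
  structure(list(family = family, nugget = nugget, sill = sill,
                 range = range), class = "variogram_model")
}

#' Evaluate a variogram model at distances h
#' @param model a `variogram_model`.
#' @param h nonnegative distances.
#' @export
vgm_gamma <- function(model, h) {
  psill <- model$sill - model$nugget
  a <- model$range
  g <- switch(model$family,
    spherical = ifelse(h >= a, psill,
                       psill * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = psill * (1 - exp(-3 * h / a)),
    gaussian = psill * (1 - exp(-3 * (h / a)^2)))
  out <- model$nugget + g
  out[h == 0] <- 0
  out
}

#' Empirical semivariogram of a 3D point set
#'
#' Bins all point pairs by 3D Euclidean distance (half-open bins
#' `[edge_i, edge_{i+1})`) and returns per-bin mean distance, semivariance
#' `(1 / 2N_b) * sum (v_i - v_j)^2`, and pair count.
#'
#' @param points matrix/data frame with columns x, y, z, value.
#' @param bin_edges increasing numeric bin edges.
#' @return data frame with columns `dist`, `gamma`, `npairs` (empty bins have
#'   `NA` gamma and zero count).
#' @export
empirical_variogram <- function(points, bin_edges) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  d <- as.vector(stats::dist(points[, 1:3, drop = FALSE]))
  v <- points[, 4]
  n <- nrow(points)
  dv2 <- as.vector(stats::dist(matrix(v, ncol = 1)))^2
  bin <- findInterval(d, bin_edges)
  inside <- bin >= 1L & d < bin_edges[length(bin_edges)]
  if (!any(inside)) stop("all point pairs fall outside the variogram bins")
  nb <- length(bin_edges) - 1L
  out <- data.frame(dist = rep(NA_real_, nb), gamma = rep(NA_real_, nb),
                    npairs = integer(nb))
  for (b in seq_len(nb)) {
    sel <- inside & bin == b
    out$npairs[b] <- sum(sel)
    if (out$npairs[b]) {
      out$dist[b] <- mean(d[sel])
      out$gamma[b] <- sum(dv2[sel]) / (2 * out$npairs[b])
    }
  }
  out
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with pair-count weights over (nugget, sill, range),
#' bound-constrained (all nonnegative, sill >= nugget). Deterministic: a
#' fixed multi-start grid over the range is refined with L-BFGS-B. A
#' degenerate fit falls back to a pure-nugget model with a warning.
#'
#' @param empirical data frame from [empirical_variogram()].
#' @param family variogram family name.
#' @return a `variogram_model`.
#' @export
fit_variogram <- function(empirical, family = "spherical") {
  emp <- empirical[!is.na(empirical$gamma) & empirical$npairs > 0, , drop = FALSE]
  if (nrow(emp) < 3L) stop("need at least 3 non-empty variogram bins")
  h <- emp$dist; g <- emp$gamma; w <- emp$npairs
  gmax <- max(g)
  if (gmax <= 0) {
    warning("constant semivariances: falling back to pure-nugget model")
    return(variogram_model(family, nugget = 0, sill = 0, range = max(h)))
  }
  sse <- function(p) {
    m <- variogram_model(family, nugget = p[1], sill = p[1] + p[2], range = p[3])
    sum(w * (vgm_gamma(m, h) - g)^2)
  }
  hmax <- max(h)
  starts <- expand.grid(nug = c(0, 0.1 * gmax),
                        psill = c(0.5, 1) * gmax,
                        rng = hmax * c(0.25, 0.5, 1, 2))
  best <- NULL; best_val <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
                   lower = c(0, 0, 1e-6 * hmax),
                   upper = c(2 * gmax, 3 * gmax, 20 * hmax)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best_val) {
      best <- fit; best_val <- fit$value
    }
  }
  if (is.null(best) || !all(is.finite(best$par)) || best$par[3] <= 1e-5 * hmax) {
    warning("degenerate variogram fit: falling back to pure-nugget model")
    s <- stats::weighted.mean(g, w)
    return(variogram_model(family, nugget = s, sill = s, range = hmax))
  }
  variogram_model(family, nugget = best$par[1],
                  sill = best$par[1] + best$par[2], range = best$par[3])
}

#' Assemble an ordinary-kriging system
#'
#' @param coords matrix with columns x, y, z (metres) of sample locations.
#' @param values observed values at the samples.
#' @param model fitted `variogram_model`.
#' @return object of class `kriging_system`.
#' @export
kriging_fit <- function(coords, values, model) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 sample locations")
  if (nrow(unique(coords)) < 2L) stop("need at least 2 distinct locations")
  n <- nrow(coords)
  G <- matrix(0, n + 1L, n + 1L)
  dm <- as.matrix(stats::dist(coords))
  G[1:n, 1:n] <- vgm_gamma(model, dm)
  G[n + 1L, 1:n] <- 1; G[1:n, n + 1L] <- 1
  structure(list(coords = coords, values = values, model = model, G = G),
            class = "kriging_system")
}

#' Ordinary-kriging prediction at query points
#'
#' Solves the semivariance-form OK system (with Lagrange multiplier) for each
#' query. Weights sum to one; with a zero nugget the predictor is exact at
#' sample locations. A singular system is retried once with 1e-10 jitter on
#' the diagonal.
#'
#' @param system a `kriging_system`.
#' @param query matrix with columns x, y, z.
#' @return list with `prediction`, `variance` (kriging variance), and
#'   `weights` (n_samples x n_queries).
#' @export
kriging3d_predict <- function(system, query) {
  query <- matrix(as.numeric(as.matrix(query)), ncol = 3)
  n <- nrow(system$coords)
  nq <- nrow(query)
  # difference-based distances: the expanded-square form cancels
  # catastrophically at coincident points and breaks exact interpolation
  d <- sqrt(outer(system$coords[, 1], query[, 1], `-`)^2 +
              outer(system$coords[, 2], query[, 2], `-`)^2 +
              outer(system$coords[, 3], query[, 3], `-`)^2)
  B <- rbind(vgm_gamma(system$model, d), rep(1, nq))
  sol <- tryCatch(solve(system$G, B), error = function(e) {
    A <- system$G
    diag(A)[1:n] <- diag(A)[1:n] + 1e-10
    tryCatch(solve(A, B), error = function(e2)
      stop("singular kriging system (after jitter retry): ",
           conditionMessage(e2)))
  })
  # one step of iterative refinement tightens the solution on
  # ill-conditioned semivariance matrices
  sol <- sol + tryCatch(solve(system$G, B - system$G %*% sol),
                        error = function(e) 0)
  w <- sol[1:n, , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- as.vector(crossprod(w, system$values))
  vari <- colSums(w * B[1:n, , drop = FALSE]) + mu
  list(prediction = pred, variance = pmax(vari, 0), weights = w)
}
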
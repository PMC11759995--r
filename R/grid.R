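# Grid tensorization: borehole records are arranged on a (depth layer, row,
# column) lattice. Rows index northing descending, columns easting ascending,
# depth layers are half-open bins [edge_i, edge_{i+1}). The result carries a
# (D, m, n, T) feature tensor, a (D, m, n) target tensor and an observation
# mask; unobserved cells are masked and excluded from every loss and metric.

num2str <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
str2num <- function(s) {
  out <- rep(NA_real_, length(s))
  ok <- s != "NA"
  out[ok] <- as.numeric(s[ok])
  out
}

#' Arrange borehole records on a 3D sample grid
#'
#' Unique horizontal locations are rank-ordered (northing descending gives
#' the row, easting ascending the column) and depths are binned by
#' `depth_edges`. Each record must land in its own cell: collisions are an
#' error, never silently averaged. Cells without a record get their
#' coordinate channels from the lattice geometry and their six soil
#' covariates by inverse-distance weighting (power 2) from the observed
#' records, so the feature tensor is finite everywhere; their target is the
#' `NA` sentinel and the mask is `FALSE`.
#'
#' @param records borehole record data frame.
#' @param m number of grid rows (northing direction).
#' @param n number of grid columns (easting direction).
#' @param depth_edges strictly increasing numeric vector of `D+1` bin edges
#'   starting at 0.
#' @return object of class `sample_grid` with elements `raw_features`
#'   `(D,m,n,T)`, `raw_target` `(D,m,n)`, `mask`, `cell_index` (source record
#'   row or `NA`), `channels`, `depth_edges`, lattice coordinate vectors, and
#'   after [normalize_grid()] also `features`, `target`, `norm`.
#' @export
build_grid <- function(records, m = 4L, n = 3L,
                       depth_edges = seq(0, 6, by = 0.5)) {
  records <- as_borehole_records(records)
  if (any(diff(depth_edges) <= 0)) stop("depth_edges must be strictly increasing")
  D <- length(depth_edges) - 1L
  ue <- sort(unique(records$easting))
  un <- sort(unique(records$northing), decreasing = TRUE)
  if (length(ue) > n)
    stop("records have ", length(ue), " distinct eastings but grid has ", n, " columns")
  if (length(un) > m)
    stop("records have ", length(un), " distinct northings but grid has ", m, " rows")
  eastings <- extend_coords(ue, n, ascending = TRUE)
  northings <- extend_coords(un, m, ascending = FALSE)
  depth_centers <- (depth_edges[-1] + depth_edges[-length(depth_edges)]) / 2

  bin <- findInterval(records$depth, depth_edges)
  bad <- which(bin < 1L | records$depth >= depth_edges[D + 1L])
  if (length(bad))
    stop("record ", bad[1], " has depth ", records$depth[bad[1]],
         " outside [", depth_edges[1], ", ", depth_edges[D + 1L], ")")
  row <- match(records$northing, northings)
  col <- match(records$easting, eastings)

  channels <- borehole_features()
  Tn <- length(channels)
  feats <- array(NA_real_, dim = c(D, m, n, Tn))
  target <- array(NA_real_, dim = c(D, m, n))
  mask <- array(FALSE, dim = c(D, m, n))
  cell_index <- array(NA_integer_, dim = c(D, m, n))

  for (i in seq_len(nrow(records))) {
    d <- bin[i]; r <- row[i]; cc <- col[i]
    if (!is.na(cell_index[d, r, cc]))
      stop("cell collision at depth bin ", d, ", row ", r, ", col ", cc,
           ": records ", cell_index[d, r, cc], " and ", i,
           " occupy the same cell")
    cell_index[d, r, cc] <- i
    for (ci in seq_len(Tn)) feats[d, r, cc, ci] <- records[[channels[ci]]][i]
    target[d, r, cc] <- records$tph[i]
    mask[d, r, cc] <- TRUE
  }

  # lattice geometry for the coordinate channels of unfilled cells
  empty <- which(!mask, arr.ind = TRUE)
  if (nrow(empty)) {
    qx <- eastings[empty[, 3]]
    qy <- northings[empty[, 2]]
    qz <- depth_centers[empty[, 1]]
    cov_cols <- channels[-(1:3)]
    covm <- as.matrix(records[cov_cols])
    pts <- cbind(records$easting, records$northing, records$depth)
    fill <- idw_predict(cbind(pts, covm), cbind(qx, qy, qz), power = 2)
    for (k in seq_len(nrow(empty))) {
      d <- empty[k, 1]; r <- empty[k, 2]; cc <- empty[k, 3]
      feats[d, r, cc, 1:3] <- c(qx[k], qy[k], qz[k])
      feats[d, r, cc, 4:Tn] <- fill[k, ]
    }
  }

  structure(list(raw_features = feats, raw_target = target, mask = mask,
                 cell_index = cell_index, channels = channels,
                 depth_edges = depth_edges, eastings = eastings,
                 northings = northings, depth_centers = depth_centers,
                 records = records, features = NULL, target = NULL,
                 norm = NULL),
            class = "sample_grid")
}

extend_coords <- function(u, k, ascending = TRUE) {
  if (length(u) == k) return(u)
  spacing <- if (length(u) >= 2) stats::median(abs(diff(u))) else 1
  extra <- seq_len(k - length(u)) * spacing
  if (ascending) c(u, max(u) + extra) else c(u, min(u) - extra)
}

#' @export
print.sample_grid <- function(x, ...) {
  d <- dim(x$raw_features)
  cat("sample_grid: D=", d[1], " m=", d[2], " n=", d[3], " channels=", d[4],
      "; observed cells: ", sum(x$mask),
      if (!is.null(x$norm)) " (normalized)", "\n", sep = "")
  invisible(x)
}

grid_dim <- function(grid) dim(grid$raw_features)

# cells: integer matrix with columns d, r, c
cells_lin <- function(grid, cells) {
  d <- grid_dim(grid)
  cells[, 1] + (cells[, 2] - 1L) * d[1] + (cells[, 3] - 1L) * d[1] * d[2]
}

observed_cells <- function(grid) {
  w <- which(grid$mask, arr.ind = TRUE)
  colnames(w) <- c("d", "r", "c")
  w
}

cell_coords <- function(grid, cells) {
  cbind(easting = grid$eastings[cells[, 3]],
        northing = grid$northings[cells[, 2]],
        depth = grid$depth_centers[cells[, 1]])
}

cell_features <- function(grid, cells, normalized = TRUE) {
  f <- if (normalized) grid$features else grid$raw_features
  if (is.null(f)) stop("grid has not been normalized; call normalize_grid()")
  d <- dim(f)
  lin <- cells_lin(grid, cells)
  out <- sapply(seq_len(d[4]), function(ci) f[lin + (ci - 1L) * d[1] * d[2] * d[3]])
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(cells))
  colnames(out) <- grid$channels
  out
}

#' Largest-remainder apportionment of n items by integer ratios
#' @keywords internal
largest_remainder <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken by partition order (train > validation > test)
    ord <- order(-(q - base), seq_along(ratios))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split observed grid cells into train/validation/test sets
#'
#' Seeded uniform shuffle of the observed cells followed by
#' largest-remainder apportionment into the given ratios (7:2:1 by default;
#' ties go to the earlier partition), so 10 cells split exactly (7, 2, 1).
#'
#' @param grid a `sample_grid`.
#' @param ratios length-3 numeric ratio (train, validation, test).
#' @param seed integer seed; identical `(grid, seed)` give identical splits.
#' @return object of class `dataset_split`: list of `train` / `validation` /
#'   `test` cell matrices plus the seed.
#' @export
split_dataset <- function(grid, ratios = c(7, 2, 1), seed = 1L) {
  cells <- observed_cells(grid)
  nobs <- nrow(cells)
  if (nobs < 10L) stop("need at least 10 observed cells to split, got ", nobs)
  sizes <- largest_remainder(nobs, ratios)
  perm <- with_seed(seed, sample.int(nobs))
  cells <- cells[perm, , drop = FALSE]
  idx <- cumsum(sizes)
  structure(list(train = cells[seq_len(idx[1]), , drop = FALSE],
                 validation = cells[(idx[1] + 1):idx[2], , drop = FALSE],
                 test = cells[(idx[2] + 1):idx[3], , drop = FALSE],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Build, split and normalize a dataset in one step
#'
#' Tensorizes the records, draws the 7:2:1 split, fits min-max normalization
#' on the training cells' records only, and applies it (with clipping) to the
#' whole grid.
#'
#' @inheritParams build_grid
#' @inheritParams split_dataset
#' @return list with `grid` (normalized), `split`, `norm`.
#' @export
prepare_dataset <- function(records, m = 4L, n = 3L,
                            depth_edges = seq(0, 6, by = 0.5),
                            ratios = c(7, 2, 1), seed = 1L) {
  grid <- build_grid(records, m = m, n = n, depth_edges = depth_edges)
  split <- split_dataset(grid, ratios = ratios, seed = seed)
  train_rows <- grid$cell_index[cells_lin(grid, split$train)]
  norm <- fit_normalization(grid$records[train_rows, , drop = FALSE])
  grid <- normalize_grid(grid, norm)
  list(grid = grid, split = split, norm = norm)
}

#' Drop a feature channel from a grid
#'
#' Rebuilds the feature tensors with one covariate channel removed (used by
#' the per-feature ablation experiment).
#'
#' @param grid a `sample_grid`.
#' @param feature channel name to remove.
#' @export
drop_channel <- function(grid, feature) {
  ci <- match(feature, grid$channels)
  if (is.na(ci)) stop("unknown feature channel: ", feature)
  grid$raw_features <- grid$raw_features[, , , -ci, drop = FALSE]
  if (!is.null(grid$features))
    grid$features <- grid$features[, , , -ci, drop = FALSE]
  grid$channels <- grid$channels[-ci]
  grid
}

# -- on-disk container --------------------------------------------------------

GRID_FORMAT_VERSION <- 1L

arr_to_json <- function(a) list(dim = dim(a), data = num2str(as.vector(a)))
json_to_arr <- function(j) array(str2num(unlist(j$data)), dim = unlist(j$dim))

#' Serialize a sample grid to a versioned JSON container
#'
#' Tensors are written as full-precision decimal strings so the round trip is
#' bit-exact.
#' @param grid a `sample_grid`.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  obj <- list(
    format_version = GRID_FORMAT_VERSION,
    channels = grid$channels,
    depth_edges = num2str(grid$depth_edges),
    eastings = num2str(grid$eastings),
    northings = num2str(grid$northings),
    depth_centers = num2str(grid$depth_centers),
    raw_features = arr_to_json(grid$raw_features),
    raw_target = arr_to_json(grid$raw_target),
    mask = list(dim = dim(grid$mask), data = as.integer(grid$mask)),
    cell_index = list(dim = dim(grid$cell_index),
                      data = ifelse(is.na(grid$cell_index), -1L,
                                    grid$cell_index)),
    normalized = !is.null(grid$norm)
  )
  if (obj$normalized) {
    obj$features <- arr_to_json(grid$features)
    obj$target <- arr_to_json(grid$target)
    obj$norm <- lapply(grid$norm, num2str)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a sample grid container written by [write_grid()]
#' @param path input path.
#' @export
read_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$format_version), GRID_FORMAT_VERSION))
    stop("unsupported grid container version: ", obj$format_version)
  ci <- array(as.integer(unlist(obj$cell_index$data)),
              dim = unlist(obj$cell_index$dim))
  ci[ci < 0] <- NA_integer_
  g <- list(raw_features = json_to_arr(obj$raw_features),
            raw_target = json_to_arr(obj$raw_target),
            mask = array(as.logical(unlist(obj$mask$data)),
                         dim = unlist(obj$mask$dim)),
            cell_index = ci,
            channels = unlist(obj$channels),
            depth_edges = str2num(unlist(obj$depth_edges)),
            eastings = str2num(unlist(obj$eastings)),
            northings = str2num(unlist(obj$northings)),
            depth_centers = str2num(unlist(obj$depth_centers)),
            records = NULL, features = NULL, target = NULL, norm = NULL)
  if (isTRUE(obj$normalized)) {
    g$features <- json_to_arr(obj$features)
    g$target <- json_to_arr(obj$target)
    g$norm <- structure(lapply(obj$norm, function(p)
      stats::setNames(str2num(unlist(p)), c("min", "max"))),
      class = "normalization_params")
  }
  structure(g, class = "sample_grid")
}
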
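# Shared fixtures, all built in code.

# n boreholes on a perfect m x n lattice, one sample per location in a single
# shallow depth layer, with simple deterministic covariates
lattice_records <- function(m = 4, n = 3, depth = 0.5, seed = 1) {
  locs <- expand.grid(r = seq_len(m), c = seq_len(n))
  set.seed(seed)
  data.frame(
    easting = 100 + (locs$c - 1) * 10,
    northing = 500 - (locs$r - 1) * 10,
    depth = depth,
    ph = 7.6 + runif(nrow(locs)) * 0.1,
    wet_bulk_density = 1.4 + runif(nrow(locs)) * 0.2,
    permeability_coefficient = runif(nrow(locs)) * 15,
    organic = 0.2 + runif(nrow(locs)) * 0.6,
    avg_water_yield = 0.02 + runif(nrow(locs)) * 0.25,
    salinity = 0.1 + runif(nrow(locs)) * 0.3,
    tph = runif(nrow(locs)))
}

# a prepared small dataset from a named scenario preset
scenario_dataset <- function(preset = "linear_oracle", seed = 1) {
  p <- scenario_params(preset, seed = seed)
  rec <- generate_field(p)
  prepare_dataset(rec, m = p$m, n = p$n, depth_edges = p$depth_edges,
                  seed = seed)
}

# small network configuration that builds quickly on a (3,4,3,C) input
tiny_model_cfg <- function(seed = 1, ...) {
  model_config(encoder_filters = c(3, 4),
               encoder_kernels = list(c(2, 2, 2), c(1, 2, 1)),
               decoder_kernels = list(c(1, 2, 1), NULL),
               dropout_rate = 0, seed = seed, ...)
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}

withr_tempfile <- function(fileext = ".tsv") tempfile(fileext = fileext)

default_schema_list <- function() {
  cols <- c(borehole_features(), "tph")
  stats::setNames(as.list(cols), cols)
}
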
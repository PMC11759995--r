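test_that("borehole tables round-trip through delimited text in file order", {
  rec <- lattice_records()[1:3, ]
  path <- withr_tempfile()
  write_boreholes(rec, path)
  back <- read_boreholes(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$easting, rec$easting)
  expect_equal(back$tph, rec$tph)
})

test_that("missing target column is allowed only when marked optional", {
  rec <- lattice_records()[1:3, ]
  rec$tph <- NULL
  path <- withr_tempfile()
  write_boreholes(rec, path)
  expect_error(read_boreholes(path), "tph")
  back <- read_boreholes(path, target_optional = TRUE)
  expect_true(all(is.na(back$tph)))
})

test_that("non-numeric cells raise a parse error citing the row", {
  rec <- lattice_records()[1:3, ]
  rec$depth <- as.character(rec$depth)
  rec$depth[2] <- "NA"
  path <- withr_tempfile()
  utils::write.table(rec, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_boreholes(path), "row 2")
})

test_that("schema mapping locates renamed columns and reports missing ones", {
  rec <- lattice_records()[1:3, ]
  names(rec)[names(rec) == "tph"] <- "hydrocarbon_index"
  path <- withr_tempfile()
  utils::write.table(rec, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sch <- default_schema_list()
  sch$tph <- "hydrocarbon_index"
  back <- read_boreholes(path, schema = sch)
  expect_equal(back$tph, rec$hydrocarbon_index)
  expect_error(read_boreholes(path, schema = list(tph = "nope")), "nope")
})

test_that("min-max parameters equal the extrema of the supplied records", {
  rec <- lattice_records()[c(1, 6, 11), ]   # three distinct locations
  rec$depth <- c(0, 3, 6)
  p <- fit_normalization(rec)
  expect_equal(unname(p$depth), c(0, 6))
  r2 <- rec[1:2, ]
  p2 <- fit_normalization(r2)
  for (f in names(p2))
    expect_equal(unname(p2[[f]]), range(r2[[f]]))
})

test_that("degenerate features are rejected by name", {
  rec <- lattice_records()[c(1, 6, 11), ]
  rec$depth <- c(0, 3, 6)
  rec$ph <- 7.65
  expect_error(fit_normalization(rec), "ph")
  expect_error(fit_normalization(rec[1, , drop = FALSE]), "2 records")
})

test_that("normalization maps endpoints to 0/1, clips, and inverts exactly", {
  p <- c(min = 0, max = 6)
  expect_equal(apply_normalization(3, p), 0.5)
  expect_equal(apply_normalization(0, p), 0)
  expect_equal(apply_normalization(6, p), 1)
  expect_equal(apply_normalization(c(-5, 99), p), c(0, 1))
  expect_equal(invert_normalization(0.5, p), 3)
  expect_equal(invert_normalization(c(0, 1), p), c(0, 6))
  set.seed(4)
  x <- runif(100, 0, 6)
  expect_all_equal(invert_normalization(apply_normalization(x, p), p), x,
                   tol = 1e-9)
})

test_that("a full single-layer lattice fills exactly its cells", {
  rec <- lattice_records()
  g <- build_grid(rec, m = 4, n = 3, depth_edges = c(0, 1))
  expect_equal(sum(g$mask), 12L)
  expect_true(all(g$mask[1, , ]))
})

test_that("cell collisions and out-of-range depths are errors", {
  rec <- lattice_records()
  rec2 <- rbind(rec, rec[1, ])
  expect_error(build_grid(rec2, 4, 3, c(0, 1)), "collision")
  rec$depth[1] <- 2
  expect_error(build_grid(rec, 4, 3, c(0, 1)), "outside")
})

test_that("143 records tensorize onto the 4x3x12 grid with one empty cell", {
  rec <- generate_field(scenario_params("paperlike", seed = 2))
  g <- build_grid(rec)
  expect_equal(sum(g$mask), 143L)
  expect_equal(dim(g$raw_features), c(12L, 4L, 3L, 9L))
  expect_true(all(is.finite(g$raw_features)))
})

test_that("grid construction is invariant to record order", {
  rec <- generate_field(scenario_params("paperlike", seed = 3))
  g1 <- build_grid(rec)
  set.seed(9)
  g2 <- build_grid(rec[sample(nrow(rec)), ])
  expect_equal(g1$raw_features, g2$raw_features)
  expect_equal(g1$raw_target, g2$raw_target)
  expect_equal(g1$mask, g2$mask)
})

test_that("7:2:1 split sizes follow largest-remainder apportionment", {
  rec <- lattice_records()
  g10 <- build_grid(rec[1:10, ], 4, 3, c(0, 1))
  s10 <- split_dataset(g10, seed = 1)
  expect_equal(sapply(s10[c("train", "validation", "test")], nrow),
               c(train = 7L, validation = 2L, test = 1L))
  rec143 <- generate_field(scenario_params("paperlike", seed = 1))
  g <- build_grid(rec143)
  s <- split_dataset(g, seed = 1)
  expect_equal(sapply(s[c("train", "validation", "test")], nrow),
               c(train = 100L, validation = 29L, test = 14L))
})

test_that("splits are deterministic, disjoint, and cover all observed cells", {
  rec <- generate_field(scenario_params("paperlike", seed = 4))
  g <- build_grid(rec)
  s1 <- split_dataset(g, seed = 7)
  s2 <- split_dataset(g, seed = 7)
  expect_identical(s1, s2)
  all_cells <- do.call(rbind, s1[c("train", "validation", "test")])
  expect_equal(nrow(all_cells), sum(g$mask))
  expect_equal(nrow(unique(as.data.frame(all_cells))), sum(g$mask))
})

test_that("normalized grids stay inside [0,1] even with out-of-range cells", {
  ds <- scenario_dataset("paperlike", seed = 5)
  expect_true(all(ds$grid$features >= 0 & ds$grid$features <= 1))
  obs <- ds$grid$target[ds$grid$mask]
  expect_true(all(obs >= 0 & obs <= 1))
})

test_that("the grid container round-trips bit-exactly", {
  ds <- scenario_dataset("paperlike", seed = 6)
  path <- withr_tempfile(fileext = ".json")
  write_grid(ds$grid, path)
  back <- read_grid(path)
  for (f in c("raw_features", "raw_target", "mask", "cell_index",
              "channels", "depth_edges", "eastings", "northings",
              "features", "target"))
    expect_identical(back[[f]], ds$grid[[f]], info = f)
  expect_equal(back$norm, ds$grid$norm)
})
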
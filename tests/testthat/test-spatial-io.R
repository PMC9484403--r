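test_that("ASCII grid read honors header, nodata and an external writer", {
  # fixture written line-by-line by independent code, not by write_raster
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner -10.5", "yllcorner 2",
               "cellsize 0.5", "NODATA_value -9999",
               "1 2 3", "4 -9999 6", "7 8 9"), path)
  g <- read_raster(path)
  expect_equal(g$spec$n_rows, 3)
  expect_equal(g$spec$n_cols, 3)
  expect_equal(g$spec$west, -10.5)
  expect_equal(g$spec$south, 2)
  expect_equal(g$spec$east, -9)
  expect_equal(g$spec$north, 3.5)
  expect_equal(sum(!is.na(g$values)), 8)
  expect_true(is.na(g$values[2, 2]))
  expect_equal(g$values[1, ], c(1, 2, 3))   # first row is northernmost
  expect_equal(g$values[3, 1], 7)
})

test_that("malformed ASCII headers fail with the offending field named", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize oops", "NODATA_value -9999", "1 2", "3 4"), path)
  expect_error(read_raster(path), "malformed header")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "NODATA_value -9999", "1 2", "3 4", "5 6"), path)
  expect_error(read_raster(path), "cellsize")
  expect_error(read_raster(path, format = "geotiff"), "not supported")
})

test_that("raster write/read round trip preserves values and spec", {
  path <- withr::local_tempfile(fileext = ".asc")
  # all-zero grid: body is zeros
  z <- raster_grid(matrix(0, 2, 2), grid_spec(0, 0, 2, 2, 1))
  write_raster(z, path)
  expect_true(all(read_raster(path)$values == 0))
  # nodata sentinel round trip
  v <- matrix(1:6 / 7, 2, 3); v[1, 2] <- NA
  g <- raster_grid(v, grid_spec(-5, -5, -2, -3, 1))
  write_raster(g, path)
  expect_match(paste(readLines(path), collapse = " "), "-9999")
  # seeded random grid, 6 significant digits documented precision
  for (seed in 1:3) {
    g <- make_test_grid(7, 5, seed = seed, na_frac = 0.2)
    write_raster(g, path)
    back <- read_raster(path)
    expect_equal(back$values, g$values, tolerance = 1e-5)
    expect_equal(back$spec$west, g$spec$west)
    expect_equal(back$spec$cell_size, g$spec$cell_size)
    expect_identical(is.na(back$values), is.na(g$values))
  }
})

test_that("occurrence cleaning removes duplicates, (0,0) and bad rows", {
  raw <- data.frame(species = "sp",
                    longitude = c(-81, -81, 0),
                    latitude = c(29, 29, 0))
  occ <- clean_occurrences(raw)
  expect_equal(nrow(occ$records), 1)
  rem <- attr(occ, "removed")
  expect_equal(unname(rem["duplicate"]), 1L)
  expect_equal(unname(rem["zero_zero"]), 1L)

  set.seed(3)
  good <- data.frame(species = "sp", longitude = runif(60, -100, -40),
                     latitude = runif(60, -30, 30))
  expect_equal(nrow(clean_occurrences(good)$records), 60)
})

test_that("cleaning matches a brute-force set filter and is idempotent", {
  set.seed(11)
  ext <- list(west = -120, east = -32, south = -36, north = 36)
  lon <- c(runif(200, -119, -33), runif(15, 10, 20), rep(0, 5))
  lat <- c(runif(200, -35, 35), runif(15, -35, 35), rep(0, 5))
  dup_idx <- sample(200, 30, replace = TRUE)
  raw <- data.frame(species = "sp",
                    longitude = c(lon, lon[dup_idx]),
                    latitude = c(lat, lat[dup_idx]))
  raw$longitude[7] <- NA
  occ <- clean_occurrences(raw, extent = ext)
  # brute force: filter then unique
  keep <- with(raw, is.finite(longitude) & is.finite(latitude) &
                 !(longitude == 0 & latitude == 0) &
                 longitude >= ext$west & longitude <= ext$east &
                 latitude >= ext$south & latitude <= ext$north)
  expected <- unique(raw[keep, c("longitude", "latitude")])
  expect_equal(nrow(occ$records), nrow(expected))
  twice <- clean_occurrences(occ, extent = ext)
  expect_equal(twice$records, occ$records)
})

test_that("minimum occurrence gate is inclusive at 50", {
  mk <- function(n) occurrence_set("sp", seq_len(n), seq_len(n))
  expect_true(min_occurrence_filter(mk(50)))
  expect_false(min_occurrence_filter(mk(49)))
  expect_true(min_occurrence_filter(mk(449)))
})

test_that("clip_extent slices by cell centers without resampling", {
  g <- make_test_grid(10, 10, seed = 5)
  same <- clip_extent(g, 0, 0, 10, 10)
  expect_equal(same$values, g$values)
  west_half <- clip_extent(g, 0, 0, 5, 10)
  expect_equal(dim(west_half$values), c(10, 5))
  expect_equal(west_half$values, g$values[, 1:5])
  # random boxes vs index-slicing oracle
  set.seed(9)
  for (i in 1:5) {
    w <- runif(1, 0, 4); e <- runif(1, 6, 10)
    s <- runif(1, 0, 4); n <- runif(1, 6, 10)
    cl <- clip_extent(g, w, s, e, n)
    cols <- which(cell_lons(g$spec) >= w & cell_lons(g$spec) <= e)
    rows <- which(cell_lats(g$spec) >= s & cell_lats(g$spec) <= n)
    expect_equal(cl$values, g$values[rows, cols, drop = FALSE])
    expect_equal(clip_extent(cl, w, s, e, n)$values, cl$values)  # idempotent
  }
  expect_error(clip_extent(g, 100, 100, 110, 110), "overlap")
})

test_that("elevation mask is strict at the cutoff and never adds cells", {
  g <- make_test_grid(6, 6, seed = 2, na_frac = 0.1)
  flat <- raster_grid(matrix(0, 6, 6), g$spec)
  expect_equal(elevation_mask(g, flat)$values, g$values)
  high <- raster_grid(matrix(11, 6, 6), g$spec)
  expect_true(all(is.na(elevation_mask(g, high)$values)))
  at10 <- raster_grid(matrix(10, 6, 6), g$spec)
  expect_equal(elevation_mask(g, at10)$values, g$values)
  set.seed(4)
  ele <- raster_grid(matrix(runif(36, 0, 20), 6, 6), g$spec)
  masked <- elevation_mask(g, ele)
  expect_lte(sum(!is.na(masked$values)), sum(!is.na(g$values)))
  expect_error(elevation_mask(g, make_test_grid(5, 6)), "specs differ")
})

test_that("occurrence CSV round trip keeps the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  occ <- occurrence_set("Avicennia germinans", c(-81.2, -80.9), c(29, 30))
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(names(back), c("species", "longitude", "latitude"))
  expect_equal(back$longitude, c(-81.2, -80.9))
})
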
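test_that("grid_spec validates its fields and alignment uses the 1e-9 tolerance", {
  expect_error(grid_spec(0, 5, 0, 0, 1), "ncols")
  expect_error(grid_spec(5, 5, 0, 0, -1), "cellsize")
  a <- grid_spec(4, 4, 10, 20, 0.5)
  b <- grid_spec(4, 4, 10 + 1e-10, 20, 0.5)
  d <- grid_spec(4, 4, 10 + 1e-6, 20, 0.5)
  expect_true(grids_aligned(a, b))
  expect_false(grids_aligned(a, d))
  expect_false(grids_aligned(a, grid_spec(4, 5, 10, 20, 0.5)))
})

test_that("climate_raster enforces dimensions and finiteness", {
  s <- grid_spec(3, 2, 0, 0, 1)
  expect_error(climate_raster(s, matrix(0, 3, 3)), "must be 2 x 3")
  expect_error(climate_raster(s, matrix(Inf, 2, 3)), "finite")
  r <- climate_raster(s, matrix(c(1, NA, 3, 4, 5, 6), 2, 3), "bio1")
  expect_equal(sum(valid_cells(r)), 5)
})

test_that("ASCII grids parse headers, sentinels and center registration", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 20",
               "cellsize 0.5", "NODATA_value -9999",
               "1 2", "3 4"), f)
  r <- read_ascii_grid(f, "bio1")
  expect_equal(r$values, matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(r$spec$xllcorner, 10)

  # nodata sentinel becomes a missing cell
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 20",
               "cellsize 0.5", "NODATA_value -9999",
               "1 -9999", "3 4"), f)
  r <- read_ascii_grid(f)
  expect_true(is.na(r$values[1, 2]))
  expect_equal(sum(valid_cells(r)), 3)

  # center registration converts to corner by half a cell; nodata defaults
  writeLines(c("ncols 2", "nrows 2", "xllcenter 10", "yllcenter 20",
               "cellsize 0.5", "1 2", "3 4"), f)
  r <- read_ascii_grid(f)
  expect_equal(r$spec$xllcorner, 9.75)
  expect_equal(r$spec$yllcorner, 19.75)
  expect_equal(r$spec$nodata_value, -9999)
})

test_that("malformed ASCII files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols two", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3 4"), f)
  expect_error(read_ascii_grid(f), "malformed header")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3"), f)
  expect_error(read_ascii_grid(f), "expected 4 data cells, found 3")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2 3 4"), f)
  expect_error(read_ascii_grid(f), "xllcorner")
})

test_that("write/read round trip preserves values to printed precision and the missing pattern exactly", {
  f <- withr::local_tempfile(fileext = ".asc")
  for (seed in 1:5) {
    r <- random_raster(10, 10, missing_frac = 0.2, seed = seed)
    for (d in c(2L, 6L)) {
      write_ascii_grid(r, f, decimals = d)
      back <- read_ascii_grid(f, r$variable)
      expect_true(grids_aligned(r$spec, back$spec))
      expect_identical(is.na(back$values), is.na(r$values))
      expect_lte(max(abs(back$values - r$values), na.rm = TRUE),
                 0.5 * 10^-d)
    }
  }
})

test_that("written tokens honour decimals and the nodata sentinel verbatim", {
  s <- grid_spec(3, 2, 0, 0, 1)
  r <- climate_raster(s, matrix(0, 2, 3), "bio1")
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f, decimals = 1L)
  toks <- unlist(strsplit(readLines(f)[7:8], " "))
  expect_true(all(toks == "0.0"))

  r$values[1, 1] <- NA
  write_ascii_grid(r, f, decimals = 1L)
  expect_identical(strsplit(readLines(f)[7], " ")[[1]][1], "-9999")
})

test_that("crop keeps cells whose centers fall in the box, on the original lattice", {
  s <- grid_spec(4, 4, 0, 0, 1)
  r <- climate_raster(s, matrix(1:16, 4, 4), "bio1")
  # full extent is the identity
  same <- crop(r, 0, 0, 4, 4)
  expect_identical(same$values, r$values)
  expect_true(grids_aligned(same$spec, r$spec))
  # exactly the NW quadrant
  nw <- crop(r, 0, 2, 2, 4)
  expect_identical(nw$values, r$values[1:2, 1:2])
  expect_equal(nw$spec$xllcorner, 0)
  expect_equal(nw$spec$yllcorner, 2)
  expect_error(crop(r, 10, 10, 11, 11), "no cell centers")
})

test_that("cropping preserves values at geographic coordinates and is idempotent", {
  r <- random_raster(12, 15, missing_frac = 0, seed = 7, cellsize = 0.25,
                     xll = -3, yll = 1)
  withr::with_seed(11, {
    for (i in 1:10) {
      box <- sort(runif(2, -3, -3 + 15 * 0.25)); boy <- sort(runif(2, 1, 4))
      cr <- tryCatch(crop(r, box[1], boy[1], box[2], boy[2]),
                     error = function(e) NULL)
      if (is.null(cr)) next
      # every output cell equals the input value at the same coordinate
      ctr <- cell_centers(cr$spec); octr <- cell_centers(r$spec)
      for (row in seq_len(cr$spec$nrows)) for (col in seq_len(cr$spec$ncols)) {
        orow <- which(abs(octr$y - ctr$y[row]) < 1e-9)
        ocol <- which(abs(octr$x - ctr$x[col]) < 1e-9)
        expect_equal(cr$values[row, col], r$values[orow, ocol])
      }
      cr2 <- crop(cr, box[1], boy[1], box[2], boy[2])
      expect_identical(cr2$values, cr$values)
      expect_true(grids_aligned(cr2$spec, cr$spec))
    }
  })
})

test_that("cell area matches the closed form and decreases with latitude", {
  s25 <- grid_spec(10, 10, 0, 0, 2.5 / 60)
  expect_equal(round(cell_area_km2(s25, 0), 2), 21.62)
  expect_equal(cell_area_km2(s25, 60), cell_area_km2(s25, 0) / 2)
  s1 <- grid_spec(10, 10, 0, 0, 1)
  expect_equal(cell_area_km2(s1, 0), 111.6^2)
  lats <- seq(0, 89, by = 1)
  areas <- cell_area_km2(s1, lats)
  expect_true(all(diff(areas) < 0))
  expect_error(cell_area_km2(s1, 90), "latitude")
})

test_that("stacks require aligned members and unique variable ids", {
  s <- grid_spec(4, 4, 0, 0, 1)
  r1 <- climate_raster(s, matrix(1, 4, 4), "bio1")
  r2 <- climate_raster(s, matrix(2, 4, 4), "bio2")
  stk <- bioclim_stack(list(r1, r2))
  expect_named(stk$layers, c("bio1", "bio2"))
  expect_error(bioclim_stack(list(r1, r1)), "unique")
  off <- climate_raster(grid_spec(4, 4, 1, 0, 1), matrix(0, 4, 4), "bio3")
  expect_error(bioclim_stack(list(r1, off)), "aligned")
})
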
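test_that("reclassification separates land, sea and landlocked depressions", {
  # 5x5 island with a walled interior depression at -30 m
  s <- grid_spec(5, 5, 0, 0, 1)
  elev <- matrix(-4000, 5, 5)
  elev[2:4, 2:4] <- 200
  elev[3, 3] <- -30
  dem <- climate_raster(s, elev, "dem")
  m0 <- reclassify_dem(dem, 0)
  expect_equal(m0$state[3, 3], MASK_LANDLOCKED)
  expect_equal(m0$state[2, 2], MASK_LAND)
  expect_equal(m0$state[1, 1], MASK_SEA)

  # at a -120 m stand the -30 m basin floor is ordinary land
  m120 <- reclassify_dem(dem, -120)
  expect_equal(m120$state[3, 3], MASK_LAND)

  # a shelf cell above the stand is land; boundary cells at the stand are sea
  s3 <- grid_spec(3, 1, 0, 0, 1)
  dem3 <- climate_raster(s3, matrix(c(-50, 10, -120), 1, 3), "dem")
  m <- reclassify_dem(dem3, -120)
  expect_equal(as.vector(m$state), c(MASK_LAND, MASK_LAND, MASK_SEA))
})

test_that("4- vs 8-connectivity decides whether diagonal straits flood", {
  # a diagonal channel of below-level cells between ocean and a basin
  s <- grid_spec(5, 5, 0, 0, 1)
  elev <- matrix(100, 5, 5)
  elev[1, ] <- -10                      # ocean border row
  elev[2, 2] <- -10                     # diagonal step from (1,1)
  elev[3, 3] <- -10                     # diagonal chain into the interior
  dem <- climate_raster(s, elev, "dem")
  m8 <- reclassify_dem(dem, 0, connectivity = 8)
  m4 <- reclassify_dem(dem, 0, connectivity = 4)
  expect_equal(m8$state[3, 3], MASK_SEA)
  expect_equal(m4$state[3, 3], MASK_LANDLOCKED)
})

test_that("the flooded set matches a breadth-first search enumeration", {
  bfs_sea <- function(elev, sl, connectivity) {
    nr <- nrow(elev); nc <- ncol(elev)
    below <- elev <= sl
    visited <- matrix(FALSE, nr, nc)
    queue <- which((row(elev) %in% c(1, nr) | col(elev) %in% c(1, nc)) &
                     below)
    visited[queue] <- TRUE
    steps <- if (connectivity == 8) {
      cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    while (length(queue) > 0) {
      cell <- queue[1]; queue <- queue[-1]
      ci <- (cell - 1) %% nr + 1; cj <- (cell - 1) %/% nr + 1
      for (k in seq_len(nrow(steps))) {
        ni <- ci + steps[k, 1]; nj <- cj + steps[k, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            below[ni, nj] && !visited[ni, nj]) {
          visited[ni, nj] <- TRUE
          queue <- c(queue, (nj - 1) * nr + ni)
        }
      }
    }
    visited
  }
  withr::with_seed(17, for (trial in 1:6) {
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    elev <- matrix(runif(nr * nc, -200, 200), nr, nc)
    sl <- runif(1, -150, 50)
    conn <- sample(c(4L, 8L), 1)
    dem <- climate_raster(grid_spec(nc, nr, 0, 0, 1), elev, "dem")
    m <- reclassify_dem(dem, sl, connectivity = conn)
    expect_identical(m$state == MASK_SEA, bfs_sea(elev, sl, conn))
  })
})

test_that("an explicit ocean seed floods regional crops whose borders are land", {
  s <- grid_spec(5, 5, 0, 0, 1)
  elev <- matrix(100, 5, 5)
  elev[3, 3] <- -10
  dem <- climate_raster(s, elev, "dem")
  expect_equal(reclassify_dem(dem, 0)$state[3, 3], MASK_LANDLOCKED)
  seed <- matrix(FALSE, 5, 5); seed[3, 3] <- TRUE
  expect_equal(reclassify_dem(dem, 0, ocean_seed = seed)$state[3, 3],
               MASK_SEA)
})

test_that("clipping passes land values through exactly and masks the rest", {
  r <- random_raster(5, 5, missing_frac = 0, seed = 3)
  all_land <- land_mask(r$spec, matrix(MASK_LAND, 5, 5), 0)
  expect_identical(clip_mask(r, all_land)$values, r$values)
  all_sea <- land_mask(r$spec, matrix(MASK_SEA, 5, 5), 0)
  expect_true(all(is.na(clip_mask(r, all_sea)$values)))
  withr::with_seed(8, {
    st <- matrix(sample(c(MASK_SEA, MASK_LAND, MASK_LANDLOCKED), 25,
                        replace = TRUE), 5, 5)
    mk <- land_mask(r$spec, st, -40)
    clipped <- clip_mask(r, mk)
    expect_equal(sum(!is.na(clipped$values)), sum(st == MASK_LAND))
    expect_identical(clipped$values[st == MASK_LAND],
                     r$values[st == MASK_LAND])
  })
})

test_that("the southern latitude cut masks exactly the land south of it", {
  # rows span latitudes from -75 to +4.5 (cellsize 1, yll = -76)
  s <- grid_spec(6, 80, 0, -76, 1)
  withr::with_seed(4, {
    st <- matrix(sample(c(MASK_SEA, MASK_LAND), 480, replace = TRUE), 80, 6)
    mk <- land_mask(s, st, 0)
    cut <- exclude_latitudes(mk, -60)
    lat <- cell_centers(s)$y
    south <- matrix(lat < -60, 80, 6)
    expect_equal(sum(cut$state == MASK_LANDLOCKED),
                 sum(st == MASK_LAND & south))
    expect_identical(cut$state[!south], st[!south])
  })
  # a mask entirely north of the cut is unchanged
  sN <- grid_spec(4, 4, 0, 10, 1)
  mkN <- land_mask(sN, matrix(MASK_LAND, 4, 4), 0)
  expect_identical(exclude_latitudes(mkN, -60)$state, mkN$state)
})

test_that("lowering sea level never converts land to sea on the synthetic DEM", {
  w <- small_world(seed = 2)
  levels <- sort(unique(w$curve$sea_level_m), decreasing = TRUE)
  prev_land <- NULL
  for (sl in levels) {
    land <- land_of(reclassify_dem(w$dem, sl))
    if (!is.null(prev_land)) expect_true(all(land[prev_land]))
    prev_land <- land
  }
})

test_that("masks write as 1/0/nodata ASCII and read back consistently", {
  w <- small_world(seed = 3)
  m <- reclassify_dem(w$dem, 0)
  r <- mask_to_raster(m)
  expect_identical(!is.na(r$values) & r$values == 1, m$state == MASK_LAND)
  expect_identical(is.na(r$values), m$state == MASK_LANDLOCKED)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f, decimals = 0L)
  back <- read_ascii_grid(f, "mask")
  expect_identical(back$values, r$values)
})
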
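make_pair <- function(vals_p, vals_l, var = "bio1") {
  s <- grid_spec(ncol(vals_p), nrow(vals_p), 0, 0, 1)
  list(isp = climate_raster(s, vals_p, var),
       isl = climate_raster(s, vals_l, var))
}

test_that("delta layers are the cellwise ISP - ISL with missing propagation", {
  p <- make_pair(matrix(250, 2, 2), matrix(206, 2, 2))
  d <- compute_delta(p$isp, p$isl)
  expect_equal(d$values, matrix(44, 2, 2))

  same <- make_pair(matrix(5, 2, 2), matrix(5, 2, 2))
  expect_equal(compute_delta(same$isp, same$isl)$values, matrix(0, 2, 2))

  p$isl$values[1, 1] <- NA
  d <- compute_delta(p$isp, p$isl)
  expect_true(is.na(d$values[1, 1]))
  expect_equal(sum(is.na(d$values)), 1)

  other <- climate_raster(p$isp$spec, matrix(1, 2, 2), "bio2")
  expect_error(compute_delta(p$isp, other), "variable mismatch")
})

test_that("scaling multiplies values and preserves the missing pattern", {
  p <- make_pair(matrix(c(250, NA, 10, 20), 2, 2),
                 matrix(c(206, 1, 2, 3), 2, 2))
  d <- compute_delta(p$isp, p$isl)
  expect_equal(scale_delta(d, 1)$values, d$values)
  z <- scale_delta(d, 0)
  expect_identical(is.na(z$values), is.na(d$values))
  expect_true(all(z$values == 0, na.rm = TRUE))
  expect_equal(scale_delta(d, 0.5)$values[1, 1], 22)
  expect_error(scale_delta(d, NaN), "finite")
})

test_that("calibration adds the scaled anomaly and clamps precipitation at zero", {
  s <- grid_spec(2, 1, 0, 0, 1)
  lgm <- climate_raster(s, matrix(c(206, 3), 1, 2), "bio12")
  dl <- compute_delta(climate_raster(s, matrix(c(250, -7), 1, 2), "bio12"),
                      lgm)
  out <- calibrate(lgm, dl)   # precipitation id: clamp defaults on
  expect_equal(out$values, matrix(c(250, 0), 1, 2))
  expect_equal(attr(out, "n_clamped"), 1L)
  raw <- calibrate(lgm, dl, clamp_nonnegative = FALSE)
  expect_equal(raw$values, matrix(c(250, -7), 1, 2))
  expect_equal(attr(raw, "n_clamped"), 0L)
})

test_that("temperature variables are never clamped even when negative", {
  s <- grid_spec(2, 1, 0, 0, 1)
  lgm <- climate_raster(s, matrix(c(-5, 2), 1, 2), "bio1")
  dl <- compute_delta(climate_raster(s, matrix(c(-20, -30), 1, 2), "bio1"),
                      lgm)
  out <- calibrate(lgm, dl)
  expect_equal(out$values, matrix(c(-20, -30), 1, 2))
  expect_equal(attr(out, "n_clamped"), 0L)
})

test_that("calibration is linear in the scale factor before clamping", {
  w <- small_world(seed = 6)
  b <- prepare_baselines(w$present, w$lgm, w$dem, w$curve)
  d <- b$deltas$bio3
  isl <- b$isl$layers$bio3
  a <- 0.4; bb <- 0.7
  lhs <- calibrate(isl, scale_delta(d, a + bb), clamp_nonnegative = FALSE)
  rhs <- calibrate(isl, scale_delta(d, a), clamp_nonnegative = FALSE)
  expect_equal(lhs$values, rhs$values + bb * d$values, tolerance = 1e-12)
})

test_that("pre-clip output increases with Ts wherever the delta is positive", {
  w <- small_world(seed = 7)
  b <- prepare_baselines(w$present, w$lgm, w$dem, w$curve)
  d <- b$deltas$bio1
  isl <- b$isl$layers$bio1
  cv <- w$curve
  ts <- c(10, 11.5, 13)
  outs <- lapply(ts, function(t)
    calibrate(isl, scale_delta(d, scale_factor(t, cv)),
              clamp_nonnegative = FALSE)$values)
  pos <- !is.na(d$values) & d$values > 0
  expect_true(all(outs[[2]][pos] > outs[[1]][pos]))
  expect_true(all(outs[[3]][pos] > outs[[2]][pos]))
})

test_that("a present-anchored period reproduces ISP and an LGM-anchored one ISL", {
  w <- small_world(seed = 1)
  cv <- factor_curve(c(0, 1), sea_levels = c(-125, 0))
  b <- prepare_baselines(w$present, w$lgm, w$dem, cv)

  lgm_stk <- generate_period_stack(w$present, w$lgm, w$dem, cv, 20,
                                   clamp = FALSE, baselines = b)
  pres_stk <- generate_period_stack(w$present, w$lgm, w$dem, cv, 30,
                                    clamp = FALSE, baselines = b)
  expect_equal(attr(lgm_stk, "scale_factor"), 0)
  expect_equal(attr(pres_stk, "scale_factor"), 1)

  for (v in c("bio1", "bio12", "bio7")) {
    land_lgm <- land_of(exclude_latitudes(reclassify_dem(w$dem, -125), -60))
    expect_equal(lgm_stk$layers[[v]]$values[land_lgm],
                 b$isl$layers[[v]]$values[land_lgm], tolerance = 1e-12)
    land_now <- land_of(exclude_latitudes(reclassify_dem(w$dem, 0), -60))
    expect_equal(pres_stk$layers[[v]]$values[land_now],
                 b$isp$layers[[v]]$values[land_now], tolerance = 1e-9)
  }
})

test_that("the output valid set is within ISL's valid set intersected with the land mask", {
  w <- small_world(seed = 9)
  stk <- generate_period_stack(w$present, w$lgm, w$dem, w$curve,
                               w$curve$age_kyr[5])
  mask <- exclude_latitudes(
    reclassify_dem(w$dem, attr(stk, "sea_level_m")), -60)
  b <- prepare_baselines(w$present, w$lgm, w$dem, w$curve)
  for (v in names(stk$layers)) {
    ok <- !is.na(stk$layers[[v]]$values)
    expect_true(all(!is.na(b$isl$layers[[v]]$values[ok])))
    expect_true(all(land_of(mask)[ok]))
  }
})

test_that("requesting an age that is not on the curve fails", {
  w <- small_world(seed = 1)
  expect_error(generate_period_stack(w$present, w$lgm, w$dem, w$curve, 25),
               "not a period")
})
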
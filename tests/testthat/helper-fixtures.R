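# Shared fixture builders. Everything is generated in code; nothing on disk.

# a small random raster with an optional missing-cell fraction
random_raster <- function(nrows = 10, ncols = 10, missing_frac = 0.1,
                          seed = 42, variable = "bio1", cellsize = 0.5,
                          xll = 0, yll = 0) {
  withr::with_seed(seed, {
    v <- matrix(stats::runif(nrows * ncols, -50, 50), nrows, ncols)
    if (missing_frac > 0) {
      n_miss <- round(missing_frac * length(v))
      v[sample(length(v), n_miss)] <- NA_real_
    }
    climate_raster(grid_spec(ncols, nrows, xll, yll, cellsize), v, variable)
  })
}

# a compact world for pipeline tests (fast: ~hundreds of cells)
small_world <- function(seed = 1, ncols = 30, nrows = 20, ...) {
  make_world(world_config(ncols = ncols, nrows = nrows, seed = seed, ...))
}

# a curve whose rows hit exact anomaly factors, for algebraic identities
factor_curve <- function(factors, ts_present = 13.90, ts_lgm = 9.46,
                         sea_levels = NULL) {
  ts <- ts_lgm + factors * (ts_present - ts_lgm)
  ages <- 10 * (2:(length(factors) + 1))
  if (is.null(sea_levels)) sea_levels <- rep(-125, length(factors))
  temperature_curve(ages, ts, sea_levels,
                    ts_present_c = ts_present, ts_lgm_c = ts_lgm)
}

# land matrix (LAND state) for a mask
land_of <- function(mask) mask$state == MASK_LAND
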
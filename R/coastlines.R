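#' Cell states of a land mask
#'
#' Integer codes used in the `state` matrix of a [land_mask()]:
#' `LAND = 1`, `SEA = 0`, `LANDLOCKED_MISSING = 2`. A landlocked-missing
#' cell lies below sea level but has no connected path to the ocean (e.g.
#' the Qattara Depression at present sea level); such areas are treated as
#' missing data rather than flooded.
#' @name mask_states
NULL

#' @rdname mask_states
#' @export
MASK_SEA <- 0L
#' @rdname mask_states
#' @export
MASK_LAND <- 1L
#' @rdname mask_states
#' @export
MASK_LANDLOCKED <- 2L

#' Construct a land mask
#'
#' @param spec A [grid_spec()].
#' @param state Integer matrix of [mask_states] codes, `nrows x ncols`.
#' @param sea_level_m The sea-level stand the mask encodes, metres.
#' @return A `land_mask`.
#' @export
land_mask <- function(spec, state, sea_level_m) {
  stopifnot(inherits(spec, "grid_spec"))
  state <- as.matrix(state)
  if (nrow(state) != spec$nrows || ncol(state) != spec$ncols)
    stop("state matrix does not match the grid spec")
  storage.mode(state) <- "integer"
  if (!all(state %in% c(MASK_SEA, MASK_LAND, MASK_LANDLOCKED)))
    stop("state codes must be 0 (sea), 1 (land) or 2 (landlocked missing)")
  structure(list(spec = spec, state = state,
                 sea_level_m = as.numeric(sea_level_m)),
            class = "land_mask")
}

#' @export
print.land_mask <- function(x, ...) {
  cat(sprintf("<land_mask> sea level %g m: %d land, %d sea, %d landlocked\n",
              x$sea_level_m, sum(x$state == MASK_LAND),
              sum(x$state == MASK_SEA), sum(x$state == MASK_LANDLOCKED)))
  invisible(x)
}

# one dilation step of a logical matrix (4- or 8-connectivity)
dilate_mask <- function(m, connectivity) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  if (connectivity == 8L) {
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
  }
  out
}

#' Reclassify a DEM into a land mask for one sea-level stand
#'
#' Cells strictly above the sea level are LAND. Cells at or below it are
#' SEA if connected (4- or 8-connectivity) to the ocean seed set, and
#' LANDLOCKED_MISSING otherwise. The seed set is every at-or-below-level
#' cell on the grid border (a global grid's borders are polar or oceanic)
#' plus, optionally, below-level cells flagged in `ocean_seed` — needed for
#' regional crops whose borders are land. No isostatic or tectonic
#' correction is applied: this is pure eustatic reclassification of
#' present-day bathymetry.
#'
#' @param dem Elevation [climate_raster()], metres; all cells valid.
#' @param sea_level_m Sea-level stand, metres relative to present.
#' @param connectivity 8 (default; diagonal straits count as water) or 4.
#' @param ocean_seed Optional logical matrix marking additional ocean seeds.
#' @return A [land_mask()].
#' @export
reclassify_dem <- function(dem, sea_level_m, connectivity = 8L,
                           ocean_seed = NULL) {
  stopifnot(inherits(dem, "climate_raster"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  v <- dem$values
  if (anyNA(v)) stop("DEM must be fully valid")
  below <- v <= sea_level_m
  nr <- nrow(v); nc <- ncol(v)

  seed <- matrix(FALSE, nr, nc)
  seed[1, ] <- TRUE; seed[nr, ] <- TRUE
  seed[, 1] <- TRUE; seed[, nc] <- TRUE
  if (!is.null(ocean_seed)) {
    if (!is.logical(ocean_seed) || !identical(dim(ocean_seed), dim(v)))
      stop("ocean_seed must be a logical matrix aligned with the DEM")
    seed <- seed | ocean_seed
  }
  sea <- seed & below
  repeat {
    grown <- dilate_mask(sea, connectivity) & below
    if (identical(grown, sea)) break
    sea <- grown
  }
  state <- matrix(MASK_LAND, nr, nc)
  state[below] <- MASK_LANDLOCKED
  state[sea] <- MASK_SEA
  land_mask(dem$spec, state, sea_level_m)
}

#' Clip a raster with a land mask
#'
#' Values on LAND cells pass through unchanged; SEA and
#' LANDLOCKED_MISSING cells become missing.
#'
#' @param raster A [climate_raster()].
#' @param mask A [land_mask()] on the same grid.
#' @return The clipped [climate_raster()].
#' @export
clip_mask <- function(raster, mask) {
  stopifnot(inherits(raster, "climate_raster"), inherits(mask, "land_mask"))
  stop_if_misaligned(raster, mask, "raster and mask")
  v <- raster$values
  v[mask$state != MASK_LAND] <- NA_real_
  climate_raster(raster$spec, v, raster$variable)
}

#' Mask out high southern latitudes
#'
#' LAND cells whose center latitude lies south of `south_cut_deg` become
#' LANDLOCKED_MISSING, excluding Antarctica from terrestrial layers.
#'
#' @param mask A [land_mask()].
#' @param south_cut_deg Latitude cut, degrees; default -60.
#' @return The modified [land_mask()].
#' @export
exclude_latitudes <- function(mask, south_cut_deg = -60) {
  stopifnot(inherits(mask, "land_mask"))
  lat <- cell_centers(mask$spec)$y
  south <- matrix(lat < south_cut_deg, nrow = mask$spec$nrows,
                  ncol = mask$spec$ncols)
  state <- mask$state
  state[south & state == MASK_LAND] <- MASK_LANDLOCKED
  land_mask(mask$spec, state, mask$sea_level_m)
}

#' Convert a land mask to a writable raster
#'
#' LAND becomes 1, SEA becomes 0, LANDLOCKED_MISSING becomes the nodata
#' sentinel (missing); the result can be written with [write_ascii_grid()].
#'
#' @param mask A [land_mask()].
#' @return A [climate_raster()] with variable id `"mask"`.
#' @export
mask_to_raster <- function(mask) {
  stopifnot(inherits(mask, "land_mask"))
  v <- matrix(NA_real_, mask$spec$nrows, mask$spec$ncols)
  v[mask$state == MASK_LAND] <- 1
  v[mask$state == MASK_SEA] <- 0
  climate_raster(mask$spec, v, "mask")
}
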
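#' Raster geometry specification
#'
#' A `grid_spec` is the geometry contract shared by every layer in a run:
#' grid dimensions, the lower-left *corner* of the lower-left cell in
#' decimal degrees, the (square) cell size, and the nodata sentinel used
#' when the grid is written to disk. All raster arithmetic in the package
#' requires operands whose specs are aligned (see [grids_aligned()]).
#'
#' @param ncols,nrows Positive integer grid dimensions.
#' @param xllcorner,yllcorner Lower-left corner of the grid, decimal degrees.
#' @param cellsize Cell side, decimal degrees; must be positive.
#' @param nodata_value Numeric sentinel written for missing cells; default
#'   -9999, the de-facto ESRI convention.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(ncols, nrows, xllcorner, yllcorner, cellsize,
                      nodata_value = -9999) {
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (is.na(ncols) || ncols < 1L) stop("ncols must be a positive integer")
  if (is.na(nrows) || nrows < 1L) stop("nrows must be a positive integer")
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  if (!is.finite(xllcorner) || !is.finite(yllcorner))
    stop("corner coordinates must be finite")
  structure(
    list(ncols = ncols, nrows = nrows,
         xllcorner = as.numeric(xllcorner),
         yllcorner = as.numeric(yllcorner),
         cellsize = as.numeric(cellsize),
         nodata_value = as.numeric(nodata_value)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, cellsize %g deg, ll corner (%g, %g), nodata %g\n",
              x$ncols, x$nrows, x$cellsize, x$xllcorner, x$yllcorner,
              x$nodata_value))
  invisible(x)
}

#' Test whether two grid specs are aligned
#'
#' Two specs are aligned iff all six fields agree, the coordinate fields to
#' within a tolerance (default 1e-9 degrees) that absorbs decimal-printing
#' jitter without masking true misalignment.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Numeric tolerance on the coordinate fields, degrees.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$xllcorner - b$xllcorner) <= tol &&
    abs(a$yllcorner - b$yllcorner) <= tol &&
    abs(a$cellsize - b$cellsize) <= tol &&
    abs(a$nodata_value - b$nodata_value) <= tol
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  sa <- if (inherits(a, "grid_spec")) a else a$spec
  sb <- if (inherits(b, "grid_spec")) b else b$spec
  if (!grids_aligned(sa, sb))
    stop(sprintf("%s are not on aligned grids", what))
  invisible(TRUE)
}

#' A single climate layer on a grid
#'
#' One bioclim variable (or DEM) on a `grid_spec`. Values are stored as a
#' `nrows x ncols` numeric matrix whose **first row is the northernmost**,
#' matching ESRI ASCII file order so I/O never flips rows. Missing cells are
#' `NA` internally; the nodata sentinel appears only on disk.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of dimension `nrows x ncols`; `NA` = missing.
#' @param variable Variable identifier, e.g. `"bio1"`; `"dem"` for elevation.
#' @return An object of class `climate_raster`.
#' @export
climate_raster <- function(spec, values, variable = "bio1") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop(sprintf("values must be %d x %d, got %d x %d",
                 spec$nrows, spec$ncols, nrow(values), ncol(values)))
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("raster cells must be finite or NA")
  structure(list(spec = spec, variable = as.character(variable),
                 values = values),
            class = "climate_raster")
}

#' @export
print.climate_raster <- function(x, ...) {
  cat(sprintf("<climate_raster> %s: %d x %d cells, %d missing\n",
              x$variable, x$spec$nrows, x$spec$ncols,
              sum(is.na(x$values))))
  invisible(x)
}

#' Per-cell validity of a raster
#' @param raster A [climate_raster()].
#' @return Logical matrix, `TRUE` where the cell holds a value.
#' @export
valid_cells <- function(raster) !is.na(raster$values)

#' Cell-center coordinates of a grid
#'
#' Row 1 is the northernmost row, so row `i` has center latitude
#' `yllcorner + (nrows - i + 0.5) * cellsize`.
#'
#' @param spec A [grid_spec()].
#' @return List with `x` (length `ncols`) and `y` (length `nrows`, north
#'   first) center coordinate vectors.
#' @export
cell_centers <- function(spec) {
  list(x = spec$xllcorner + (seq_len(spec$ncols) - 0.5) * spec$cellsize,
       y = spec$yllcorner + (spec$nrows - seq_len(spec$nrows) + 0.5) *
         spec$cellsize)
}

#' A stack of aligned bioclim layers
#'
#' @param layers Named list of [climate_raster()] objects (names are the
#'   variable ids); all must share one aligned `grid_spec`.
#' @return An object of class `bioclim_stack`.
#' @export
bioclim_stack <- function(layers) {
  if (length(layers) == 0L) stop("a stack needs at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- vapply(layers, function(l) l$variable, character(1))
  if (anyDuplicated(names(layers)))
    stop("variable ids in a stack must be unique")
  spec <- layers[[1]]$spec
  for (l in layers) stop_if_misaligned(spec, l, "stack members")
  structure(list(spec = spec, layers = layers), class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("<bioclim_stack> %d layers (%s) on %d x %d grid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$spec$nrows, x$spec$ncols))
  invisible(x)
}

#' The 19 bioclim variable identifiers
#'
#' `bio1`-`bio11` summarise temperature, `bio12`-`bio19` precipitation;
#' the split controls which variables are clamped at zero after anomaly
#' calibration.
#' @return Character vector `c("bio1", ..., "bio19")`.
#' @export
bioclim_vars <- function() paste0("bio", 1:19)

#' Precipitation variable ids (clamped at zero by default)
#' @return Character vector `c("bio12", ..., "bio19")`.
#' @export
precipitation_vars <- function() paste0("bio", 12:19)

#' Crop a raster to a bounding box
#'
#' Keeps the whole cells whose centers fall inside the box (edges
#' inclusive); the output spec's corner lands on the original cell lattice,
#' so no resampling occurs.
#'
#' @param raster A [climate_raster()].
#' @param west,south,east,north Bounding box, decimal degrees.
#' @return The cropped [climate_raster()].
#' @export
crop <- function(raster, west, south, east, north) {
  stopifnot(inherits(raster, "climate_raster"))
  if (west >= east || south >= north) stop("degenerate bounding box")
  ctr <- cell_centers(raster$spec)
  cols <- which(ctr$x >= west & ctr$x <= east)
  rows <- which(ctr$y >= south & ctr$y <= north)
  if (length(cols) == 0L || length(rows) == 0L)
    stop("bounding box contains no cell centers")
  s <- raster$spec
  newspec <- grid_spec(
    ncols = length(cols), nrows = length(rows),
    xllcorner = s$xllcorner + (min(cols) - 1L) * s$cellsize,
    yllcorner = s$yllcorner + (s$nrows - max(rows)) * s$cellsize,
    cellsize = s$cellsize, nodata_value = s$nodata_value)
  climate_raster(newspec, raster$values[rows, cols, drop = FALSE],
                 raster$variable)
}

#' Area of one grid cell at a given latitude
#'
#' Small-cell approximation: `(cellsize * K) * (cellsize * K * cos(lat))`
#' square kilometres, with `K` kilometres per degree. The default
#' `K = 111.6` reproduces the conventional 4.65 km side (hence 21.62 km²)
#' of a 2.5 arc-minute cell at the equator.
#'
#' @param spec A [grid_spec()] (only `cellsize` is used).
#' @param latitude Degrees, `|latitude| < 90`.
#' @param km_per_deg Kilometres per degree of arc; default 111.6.
#' @return Cell area in km².
#' @export
cell_area_km2 <- function(spec, latitude, km_per_deg = 111.6) {
  stopifnot(inherits(spec, "grid_spec"))
  if (any(abs(latitude) >= 90)) stop("|latitude| must be < 90")
  side <- spec$cellsize * km_per_deg
  side * side * cos(latitude * pi / 180)
}
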
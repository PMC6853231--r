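#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (keywords case-insensitive: `ncols`,
#' `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' optional `NODATA_value`) followed by whitespace-separated values, rows
#' north to south. Center-registered headers (`xllcenter`/`yllcenter`) are
#' converted to the package's canonical corner registration by subtracting
#' half a cell. A missing `NODATA_value` defaults to -9999. Cells equal to
#' the sentinel become `NA`.
#'
#' @param path Path to the `.asc` file.
#' @param variable Variable id to attach to the returned raster; default
#'   the file name without extension.
#' @return A [climate_raster()].
#' @export
read_ascii_grid <- function(path, variable = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(variable))
    variable <- sub("\\.[^.]*$", "", basename(path))
  con <- file(path, "r")
  on.exit(close(con))

  hdr <- list()
  n_header <- 0L
  repeat {
    pos_line <- readLines(con, n = 1L)
    if (length(pos_line) == 0L) break
    toks <- strsplit(trimws(pos_line), "\\s+")[[1]]
    if (length(toks) == 0L || toks[1] == "") { n_header <- n_header + 1L; next }
    key <- tolower(toks[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                   "yllcorner", "yllcenter", "cellsize", "nodata_value")) {
      if (length(toks) != 2L || is.na(suppressWarnings(as.numeric(toks[2]))))
        stop("malformed header line in ", path, ": '", pos_line, "'")
      hdr[[key]] <- as.numeric(toks[2])
      n_header <- n_header + 1L
    } else break  # first data line reached
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]]))
      stop("header of ", path, " lacks required keyword '", req, "'")
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("header of ", path, " lacks xllcorner/xllcenter")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("header of ", path, " lacks yllcorner/yllcenter")

  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999

  spec <- grid_spec(hdr$ncols, hdr$nrows, xll, yll, hdr$cellsize, nodata)

  # re-scan the whole file, skipping the header lines, for speed
  close(con); on.exit()
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != spec$ncols * spec$nrows)
    stop(sprintf("%s: expected %d data cells, found %d",
                 path, spec$ncols * spec$nrows, length(vals)))
  m <- matrix(vals, nrow = spec$nrows, ncol = spec$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  climate_raster(spec, m, variable)
}

#' Write an ESRI ASCII grid
#'
#' Emits the standard 6-line corner-registered header, then
#' space-separated rows north first. Valid values are printed with
#' `decimals` fractional digits; missing cells are printed as the nodata
#' sentinel verbatim (no decimal expansion).
#'
#' @param raster A [climate_raster()].
#' @param path Output path.
#' @param decimals Fractional digits to print; default 4.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, decimals = 4L) {
  stopifnot(inherits(raster, "climate_raster"))
  s <- raster$spec
  nodata_tok <- format(s$nodata_value, scientific = FALSE, trim = TRUE)
  header <- c(
    sprintf("ncols %d", s$ncols),
    sprintf("nrows %d", s$nrows),
    sprintf("xllcorner %.10g", s$xllcorner),
    sprintf("yllcorner %.10g", s$yllcorner),
    sprintf("cellsize %.10g", s$cellsize),
    sprintf("NODATA_value %s", nodata_tok))
  toks <- formatC(raster$values, format = "f", digits = decimals)
  toks[is.na(raster$values)] <- nodata_tok
  dim(toks) <- dim(raster$values)
  rows <- apply(toks, 1L, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ", path)
  invisible(path)
}

#' Read a directory of per-variable ASCII grids as a stack
#'
#' Expects files named `<var>.asc` (e.g. `bio1.asc`); all must align.
#'
#' @param dir Directory containing `.asc` layers.
#' @param vars Optional character vector restricting which variables to load.
#' @return A [bioclim_stack()].
#' @export
read_stack_dir <- function(dir, vars = NULL) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (length(files) == 0L) stop("no .asc layers in ", dir)
  ids <- sub("\\.asc$", "", basename(files))
  if (!is.null(vars)) {
    keep <- ids %in% vars
    if (!any(keep)) stop("none of the requested variables found in ", dir)
    files <- files[keep]; ids <- ids[keep]
  }
  ord <- order(suppressWarnings(as.integer(sub("^bio", "", ids))), ids,
               na.last = TRUE)
  layers <- lapply(seq_along(files)[ord], function(i)
    read_ascii_grid(files[i], variable = ids[i]))
  bioclim_stack(layers)
}

#' Write a stack as one ASCII grid per variable
#'
#' @param stack A [bioclim_stack()].
#' @param dir Output directory (created if needed).
#' @param decimals Fractional digits for [write_ascii_grid()].
#' @return `dir`, invisibly.
#' @export
write_stack_dir <- function(stack, dir, decimals = 4L) {
  stopifnot(inherits(stack, "bioclim_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in names(stack$layers))
    write_ascii_grid(stack$layers[[v]], file.path(dir, paste0(v, ".asc")),
                     decimals = decimals)
  invisible(dir)
}
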
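#' Run configuration for the full layer-generation pipeline
#'
#' Bundles input paths or in-memory objects, the period and variable
#' selection, interpolation settings and output location. Inputs may be
#' given either as directories / files (`present_dir`, `lgm_dir`,
#' `dem_path`, `curve_path`) or as already-loaded objects (`present`,
#' `lgm`, `dem`, `curve`); objects win when both are present.
#'
#' @param present_dir,lgm_dir Directories of per-variable `.asc` layers.
#' @param dem_path,curve_path DEM `.asc` and curve CSV paths.
#' @param present,lgm,dem,curve In-memory alternatives.
#' @param out_dir Output directory; one `"<age>kyr"` subdirectory per
#'   period is written.
#' @param vars Variable subset; `NULL` = all shared variables.
#' @param periods Numeric ages (kyr) to generate; `NULL` = every curve row.
#' @param bbox Optional `c(west, south, east, north)` crop applied to all
#'   inputs before processing.
#' @param fill A [fill_config()].
#' @param clamp Clamp negative precipitation to zero; default `TRUE`.
#' @param connectivity Land-mask flood-fill connectivity; default 8.
#' @param south_cut_deg Southern latitude cut; default -60, `NULL` to skip.
#' @param ts_present_c,ts_lgm_c Optional anchor overrides for a curve
#'   loaded from `curve_path`.
#' @param decimals Fractional digits in output grids; default 4.
#' @param log_path JSON-lines run-log path; default
#'   `file.path(out_dir, "run_log.jsonl")`.
#' @return A `run_config` list.
#' @export
run_config <- function(present_dir = NULL, lgm_dir = NULL, dem_path = NULL,
                       curve_path = NULL, present = NULL, lgm = NULL,
                       dem = NULL, curve = NULL, out_dir = "out",
                       vars = NULL, periods = NULL, bbox = NULL,
                       fill = fill_config(), clamp = TRUE,
                       connectivity = 8L, south_cut_deg = -60,
                       ts_present_c = NULL, ts_lgm_c = NULL,
                       decimals = 4L, log_path = NULL) {
  structure(list(present_dir = present_dir, lgm_dir = lgm_dir,
                 dem_path = dem_path, curve_path = curve_path,
                 present = present, lgm = lgm, dem = dem, curve = curve,
                 out_dir = out_dir, vars = vars, periods = periods,
                 bbox = bbox, fill = fill, clamp = clamp,
                 connectivity = as.integer(connectivity),
                 south_cut_deg = south_cut_deg,
                 ts_present_c = ts_present_c, ts_lgm_c = ts_lgm_c,
                 decimals = as.integer(decimals),
                 log_path = log_path %||%
                   file.path(out_dir, "run_log.jsonl")),
            class = "run_config")
}

load_run_inputs <- function(config) {
  present <- config$present %||% {
    if (is.null(config$present_dir)) stop("no present-day stack supplied")
    read_stack_dir(config$present_dir, config$vars)
  }
  lgm <- config$lgm %||% {
    if (is.null(config$lgm_dir)) stop("no LGM stack supplied")
    read_stack_dir(config$lgm_dir, config$vars)
  }
  dem <- config$dem %||% {
    if (is.null(config$dem_path)) stop("no DEM supplied")
    read_ascii_grid(config$dem_path, variable = "dem")
  }
  curve <- config$curve %||% {
    if (is.null(config$curve_path)) stop("no curve supplied")
    load_curve(config$curve_path, ts_present_c = config$ts_present_c,
               ts_lgm_c = config$ts_lgm_c)
  }
  if (!is.null(config$vars)) {
    keep <- intersect(config$vars, names(present$layers))
    if (length(keep) == 0L) stop("requested variables not in present stack")
    present <- bioclim_stack(present$layers[keep])
    keep <- intersect(config$vars, names(lgm$layers))
    if (length(keep) == 0L) stop("requested variables not in LGM stack")
    lgm <- bioclim_stack(lgm$layers[keep])
  }
  if (!is.null(config$bbox)) {
    b <- config$bbox
    crop_all <- function(stk) bioclim_stack(
      lapply(stk$layers, crop, west = b[1], south = b[2], east = b[3],
             north = b[4]))
    present <- crop_all(present); lgm <- crop_all(lgm)
    dem <- crop(dem, b[1], b[2], b[3], b[4])
  }
  list(present = present, lgm = lgm, dem = dem, curve = curve)
}

#' Generate clipped palaeo-bioclim layers for many periods
#'
#' The end-to-end pipeline: gap-fill ISP / ISL once, then for every
#' requested period scale the delta layers by the period's anomaly
#' factor, calibrate them on the gap-filled LGM baseline, clip with the
#' period's sea-level land mask, and write one ASCII grid per variable
#' to `out/<age>kyr/<var>.asc`. A JSON-lines run log records, per period,
#' the age, Ts, anomaly factor, sea level and the per-variable clamp and
#' missing-cell counts. Land masks are cached by sea level, so curves
#' that revisit a stand (as glacial cycles do) cost one flood fill per
#' distinct level.
#'
#' @param config A [run_config()].
#' @return Invisibly, a data frame with one row per period (age, ts,
#'   factor, sea level, output directory).
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_run_inputs(config)
  periods <- config$periods %||% inp$curve$age_kyr
  if (length(periods) == 0L) stop("no periods selected")
  missing_ages <- setdiff(periods, inp$curve$age_kyr)
  if (length(missing_ages) > 0L)
    stop("ages not on the curve: ", paste(missing_ages, collapse = ", "))

  base <- prepare_baselines(inp$present, inp$lgm, inp$dem, inp$curve,
                            config$fill)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(config$log_path, "w")
  on.exit(close(logcon))

  mask_cache <- new.env(parent = emptyenv())
  period_mask <- function(sl) {
    key <- sprintf("%.9g", sl)
    if (is.null(mask_cache[[key]])) {
      m <- reclassify_dem(inp$dem, sl, connectivity = config$connectivity)
      if (!is.null(config$south_cut_deg))
        m <- exclude_latitudes(m, config$south_cut_deg)
      mask_cache[[key]] <- m
    }
    mask_cache[[key]]
  }

  rows <- vector("list", length(periods))
  for (pi in seq_along(periods)) {
    age <- periods[pi]
    row <- which(inp$curve$age_kyr == age)
    f <- scale_factor(inp$curve$ts_c[row], inp$curve)
    sl <- inp$curve$sea_level_m[row]
    mask <- period_mask(sl)
    pdir <- file.path(config$out_dir, sprintf("%gkyr", age))
    dir.create(pdir, showWarnings = FALSE)
    per_var <- list()
    for (v in names(base$deltas)) {
      out <- tryCatch({
        scaled <- scale_delta(base$deltas[[v]], f)
        cal <- calibrate(base$isl$layers[[v]], scaled,
                         clamp_nonnegative = config$clamp &&
                           v %in% precipitation_vars())
        clipped <- clip_mask(cal, mask)
        attr(clipped, "n_clamped") <- attr(cal, "n_clamped")
        clipped
      }, error = function(e)
        stop(sprintf("period %g kyr, variable %s: %s", age, v,
                     conditionMessage(e)), call. = FALSE))
      write_ascii_grid(out, file.path(pdir, paste0(v, ".asc")),
                       decimals = config$decimals)
      per_var[[v]] <- list(n_clamped = attr(out, "n_clamped"),
                           n_missing = sum(is.na(out$values)))
    }
    writeLines(jsonlite::toJSON(
      list(age_kyr = age, ts_c = inp$curve$ts_c[row], factor = f,
           sea_level_m = sl, variables = per_var),
      auto_unbox = TRUE, digits = NA), logcon)
    rows[[pi]] <- data.frame(age_kyr = age, ts_c = inp$curve$ts_c[row],
                             factor = f, sea_level_m = sl, dir = pdir)
  }
  invisible(do.call(rbind, rows))
}

#' Write one land mask per period
#'
#' Reclassifies the DEM at each period's sea level and writes the masks
#' as ASCII grids (`mask_<age>kyr.asc`; LAND = 1, SEA = 0,
#' landlocked-missing = nodata).
#'
#' @param dem Elevation [climate_raster()] or `.asc` path.
#' @param curve A [temperature_curve()] or curve CSV path.
#' @param out_dir Output directory.
#' @param periods Ages to process; `NULL` = all curve rows.
#' @param connectivity Flood-fill connectivity; default 8.
#' @param south_cut_deg Southern latitude cut; default -60.
#' @return Invisibly, the vector of files written.
#' @export
run_masks <- function(dem, curve, out_dir, periods = NULL,
                      connectivity = 8L, south_cut_deg = -60) {
  if (is.character(dem)) dem <- read_ascii_grid(dem, variable = "dem")
  if (is.character(curve)) curve <- load_curve(curve)
  periods <- periods %||% curve$age_kyr
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (age in periods) {
    row <- which(curve$age_kyr == age)
    if (length(row) != 1L) stop("age ", age, " is not on the curve")
    m <- reclassify_dem(dem, curve$sea_level_m[row],
                        connectivity = connectivity)
    if (!is.null(south_cut_deg)) m <- exclude_latitudes(m, south_cut_deg)
    p <- file.path(out_dir, sprintf("mask_%gkyr.asc", age))
    write_ascii_grid(mask_to_raster(m), p, decimals = 0L)
    files <- c(files, p)
  }
  invisible(files)
}

#' Validate one layer directory against another
#'
#' Reads the two directories as stacks and writes the per-variable
#' comparison table (Pearson r, absolute-difference quantiles, joint
#' cell counts) as CSV.
#'
#' @param a_dir,b_dir Directories of `.asc` layers with matching names.
#' @param report_path Output CSV path.
#' @param vars Optional variable subset.
#' @return The comparison data frame, invisibly.
#' @export
run_validate <- function(a_dir, b_dir, report_path, vars = NULL) {
  a <- read_stack_dir(a_dir, vars)
  b <- read_stack_dir(b_dir, vars)
  invisible(compare_stacks(a, b, report = report_path))
}

#' Write a synthetic world to disk
#'
#' Materialises [make_world()] in the formats the pipeline consumes:
#' `present/` and `lgm/` layer directories, `dem.asc` and `curve.csv`.
#'
#' @param out_dir Output directory.
#' @param config A [world_config()].
#' @param decimals Fractional digits for the layers; default 4.
#' @return Invisibly, `out_dir`.
#' @export
run_synth <- function(out_dir, config = world_config(), decimals = 4L) {
  w <- make_world(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack_dir(w$present, file.path(out_dir, "present"), decimals)
  write_stack_dir(w$lgm, file.path(out_dir, "lgm"), decimals)
  write_ascii_grid(w$dem, file.path(out_dir, "dem.asc"), decimals)
  write_curve(w$curve, file.path(out_dir, "curve.csv"))
  invisible(out_dir)
}
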
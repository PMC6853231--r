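#' Compute an anomaly (delta) layer
#'
#' The cellwise difference ISP - ISL between the gap-filled present and
#' LGM surfaces of one variable: the spatial fingerprint of glacial
#' climate change that is later rescaled through the temperature curve.
#' Valid exactly where both inputs are valid.
#'
#' @param isp Interpolated present surface, a [climate_raster()].
#' @param isl Interpolated LGM surface, same variable and grid.
#' @return A `delta_layer`: a [climate_raster()] with class
#'   `c("delta_layer", "climate_raster")` and a `provenance` attribute.
#' @export
compute_delta <- function(isp, isl) {
  stopifnot(inherits(isp, "climate_raster"), inherits(isl, "climate_raster"))
  if (!identical(isp$variable, isl$variable))
    stop(sprintf("variable mismatch: '%s' vs '%s'", isp$variable,
                 isl$variable))
  stop_if_misaligned(isp, isl, "ISP and ISL")
  d <- climate_raster(isp$spec, isp$values - isl$values, isp$variable)
  class(d) <- c("delta_layer", class(d))
  attr(d, "provenance") <- c(isp = "ISP", isl = "ISL")
  d
}

#' Scale a delta layer by the period's anomaly factor
#'
#' Cellwise multiplication; the missing pattern is preserved. The factor
#' comes from [scale_factor()] and may lie outside [0, 1].
#'
#' @param delta A delta layer from [compute_delta()].
#' @param factor Finite dimensionless scalar.
#' @return The scaled delta layer.
#' @export
scale_delta <- function(delta, factor) {
  stopifnot(inherits(delta, "climate_raster"))
  if (!is.finite(factor)) stop("factor must be finite")
  out <- climate_raster(delta$spec, delta$values * factor, delta$variable)
  class(out) <- class(delta)
  attr(out, "provenance") <- attr(delta, "provenance")
  out
}

#' Calibrate a scaled anomaly onto the glacial baseline
#'
#' Adds the scaled delta to the LGM baseline cellwise (valid where both
#' are valid), producing the period's layer. For precipitation variables
#' negative results are physically meaningless, so `clamp_nonnegative`
#' (default) sets them to 0; the count of clamped cells is attached as
#' attribute `n_clamped` for the run log.
#'
#' @param lgm_baseline The (gap-filled) LGM layer, a [climate_raster()].
#' @param scaled_delta The scaled delta layer, same variable and grid.
#' @param clamp_nonnegative Clamp negative results to zero; default `TRUE`
#'   for precipitation ids (`bio12`-`bio19`), `FALSE` otherwise.
#' @return The period's [climate_raster()] with attribute `n_clamped`.
#' @export
calibrate <- function(lgm_baseline, scaled_delta,
                      clamp_nonnegative =
                        lgm_baseline$variable %in% precipitation_vars()) {
  stopifnot(inherits(lgm_baseline, "climate_raster"),
            inherits(scaled_delta, "climate_raster"))
  if (!identical(lgm_baseline$variable, scaled_delta$variable))
    stop(sprintf("variable mismatch: '%s' vs '%s'", lgm_baseline$variable,
                 scaled_delta$variable))
  stop_if_misaligned(lgm_baseline, scaled_delta, "baseline and delta")
  v <- lgm_baseline$values + scaled_delta$values
  n_clamped <- 0L
  if (isTRUE(clamp_nonnegative)) {
    neg <- !is.na(v) & v < 0
    n_clamped <- sum(neg)
    v[neg] <- 0
  }
  out <- climate_raster(lgm_baseline$spec, v, lgm_baseline$variable)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Precompute the period-independent pipeline state
#'
#' Gap-fills the present and LGM stacks over the shelf (ISP / ISL) and
#' computes their delta layers once; every period is then pure raster
#' algebra on this cache. The shelf target mask is derived from the DEM
#' and the lowest sea level of the curve.
#'
#' @param present,lgm Present-day and LGM [bioclim_stack()]s.
#' @param dem Elevation [climate_raster()], metres.
#' @param curve A [temperature_curve()] (its minimum sea level defines
#'   the shelf).
#' @param fill A [fill_config()].
#' @return List with `isp`, `isl` (filled stacks), `deltas` (named list of
#'   delta layers) and `target_mask`.
#' @export
prepare_baselines <- function(present, lgm, dem, curve,
                              fill = fill_config()) {
  stopifnot(inherits(present, "bioclim_stack"),
            inherits(lgm, "bioclim_stack"))
  stop_if_misaligned(present, lgm, "present and LGM stacks")
  stop_if_misaligned(present, dem, "stacks and DEM")
  vars <- intersect(names(present$layers), names(lgm$layers))
  if (length(vars) == 0L) stop("present and LGM stacks share no variables")
  tmask <- shelf_target_mask(dem, min(curve$sea_level_m))
  isp <- fill_stack(bioclim_stack(present$layers[vars]), tmask, fill)
  isl <- fill_stack(bioclim_stack(lgm$layers[vars]), tmask, fill)
  deltas <- lapply(vars, function(v)
    compute_delta(isp$layers[[v]], isl$layers[[v]]))
  names(deltas) <- vars
  list(isp = isp, isl = isl, deltas = deltas, target_mask = tmask)
}

#' Generate the clipped bioclim stack for one time period
#'
#' Runs the full per-period chain for all shared variables: scale each
#' delta by the period's factor, add it to the gap-filled LGM baseline,
#' and clip with the land mask for the period's sea level (landlocked
#' depressions become missing). Pass a precomputed `baselines` cache when
#' generating many periods.
#'
#' @param present,lgm Present-day and LGM [bioclim_stack()]s.
#' @param dem Elevation [climate_raster()], metres.
#' @param curve A [temperature_curve()].
#' @param age_kyr Age of the requested period; must be a row of the curve.
#' @param fill A [fill_config()].
#' @param clamp If `TRUE` (default) precipitation variables are clamped at
#'   zero after calibration.
#' @param connectivity Flood-fill connectivity for the land mask, 8 or 4.
#' @param south_cut_deg Southern latitude cut (default -60); `NULL` skips
#'   the cut.
#' @param baselines Optional cache from [prepare_baselines()].
#' @return A [bioclim_stack()]; each layer carries `n_clamped`, the stack
#'   carries attributes `scale_factor`, `sea_level_m`, `ts_c`.
#' @export
generate_period_stack <- function(present, lgm, dem, curve, age_kyr,
                                  fill = fill_config(), clamp = TRUE,
                                  connectivity = 8L, south_cut_deg = -60,
                                  baselines = NULL) {
  row <- which(curve$age_kyr == age_kyr)
  if (length(row) != 1L)
    stop("age ", age_kyr, " kyr is not a period of the curve")
  if (is.null(baselines))
    baselines <- prepare_baselines(present, lgm, dem, curve, fill)
  f <- scale_factor(curve$ts_c[row], curve)
  sl <- curve$sea_level_m[row]
  mask <- reclassify_dem(dem, sl, connectivity = connectivity)
  if (!is.null(south_cut_deg)) mask <- exclude_latitudes(mask, south_cut_deg)

  layers <- lapply(names(baselines$deltas), function(v) {
    scaled <- scale_delta(baselines$deltas[[v]], f)
    cal <- calibrate(baselines$isl$layers[[v]], scaled,
                     clamp_nonnegative = clamp &&
                       v %in% precipitation_vars())
    out <- clip_mask(cal, mask)
    attr(out, "n_clamped") <- attr(cal, "n_clamped")
    out
  })
  names(layers) <- names(baselines$deltas)
  stk <- bioclim_stack(layers)
  attr(stk, "scale_factor") <- f
  attr(stk, "sea_level_m") <- sl
  attr(stk, "ts_c") <- curve$ts_c[row]
  attr(stk, "age_kyr") <- age_kyr
  stk
}
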
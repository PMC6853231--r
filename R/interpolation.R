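#' Gap-filling configuration
#'
#' Controls how present / LGM surfaces are extended over now-submerged
#' shelf cells. Both interpolators are exact (source cells are never
#' altered) and local: only the `max_neighbors` nearest source cells within
#' `search_radius_cells` contribute, so mid-ocean cells stay missing rather
#' than receiving long-range extrapolations. Distances are Euclidean in
#' cell units on the grid (a deliberate shelf-local simplification; see the
#' methods vignette for the polar caveat).
#'
#' @param method `"idw"` (inverse distance weighting, default) or
#'   `"ordinary_kriging"`.
#' @param idw_power Positive IDW exponent; default 2.
#' @param max_neighbors Number of nearest source cells used per target;
#'   default 12. Equal distances are broken by (row, col) ascending so
#'   outputs are reproducible.
#' @param search_radius_cells Maximum source distance in cell units;
#'   default 25. Targets with no source inside the radius stay missing.
#' @param variogram_model Kriging variogram family, `"exponential"`
#'   (default) or `"spherical"`.
#' @return A `fill_config` list.
#' @export
fill_config <- function(method = c("idw", "ordinary_kriging"),
                        idw_power = 2, max_neighbors = 12L,
                        search_radius_cells = 25,
                        variogram_model = c("exponential", "spherical")) {
  method <- match.arg(method)
  variogram_model <- match.arg(variogram_model)
  if (!is.finite(idw_power) || idw_power <= 0) stop("idw_power must be > 0")
  if (max_neighbors < 1L) stop("max_neighbors must be >= 1")
  if (!is.finite(search_radius_cells) || search_radius_cells <= 0)
    stop("search_radius_cells must be > 0")
  structure(list(method = method, idw_power = idw_power,
                 max_neighbors = as.integer(max_neighbors),
                 search_radius_cells = search_radius_cells,
                 variogram_model = variogram_model),
            class = "fill_config")
}

#' Shelf cells that need gap-filling
#'
#' True exactly where the DEM is at or below present sea level (0 m) but
#' above the lowest sea-level stand of the timeline: the cells that are
#' submerged today yet become land at some point, so the climate surfaces
#' need values there.
#'
#' @param dem Elevation [climate_raster()], metres.
#' @param lowest_sea_level_m Lowest stand of the sea-level series, metres
#'   (negative).
#' @return Logical matrix, `TRUE` on fill targets.
#' @export
shelf_target_mask <- function(dem, lowest_sea_level_m) {
  stopifnot(inherits(dem, "climate_raster"))
  v <- dem$values
  !is.na(v) & v <= 0 & v > lowest_sea_level_m
}

#' Extend a surface over target cells by local exact interpolation
#'
#' Every originally valid cell keeps its exact value. Every target cell
#' (`TRUE` in `target_mask` and missing in the input) within
#' `search_radius_cells` of at least one source cell receives a value
#' interpolated from its `max_neighbors` nearest source cells (IDW or
#' local ordinary kriging per `config`); unreachable targets stay missing.
#' A target that coincides with a source distance 0 is given that source's
#' value exactly.
#'
#' @param raster Input [climate_raster()]; its valid cells are the sources.
#' @param target_mask Logical matrix aligned with the raster.
#' @param config A [fill_config()].
#' @return The filled [climate_raster()], with attribute `n_unreachable`
#'   counting targets left missing.
#' @export
fill_surface <- function(raster, target_mask, config = fill_config()) {
  stopifnot(inherits(raster, "climate_raster"), inherits(config, "fill_config"))
  if (!is.logical(target_mask) ||
      !identical(dim(target_mask), dim(raster$values)))
    stop("target_mask must be a logical matrix aligned with the raster")
  src <- which(!is.na(raster$values), arr.ind = TRUE)
  if (nrow(src) == 0L) stop("no valid source cells to interpolate from")
  tgt <- which(target_mask & is.na(raster$values), arr.ind = TRUE)
  out <- raster$values
  if (nrow(tgt) == 0L) {
    attr(out, "n_unreachable") <- NULL
    res <- climate_raster(raster$spec, out, raster$variable)
    attr(res, "n_unreachable") <- 0L
    return(res)
  }

  src_vals <- raster$values[src]
  vg <- NULL
  if (config$method == "ordinary_kriging")
    vg <- fit_variogram(src, src_vals, config$variogram_model)

  r2max <- config$search_radius_cells^2
  n_unreachable <- 0L
  for (i in seq_len(nrow(tgt))) {
    dr <- src[, 1L] - tgt[i, 1L]
    dc <- src[, 2L] - tgt[i, 2L]
    d2 <- dr * dr + dc * dc
    inr <- which(d2 <= r2max)
    if (length(inr) == 0L) { n_unreachable <- n_unreachable + 1L; next }
    # nearest max_neighbors, ties broken by (row, col) ascending
    ord <- inr[order(d2[inr], src[inr, 1L], src[inr, 2L])]
    nb <- ord[seq_len(min(config$max_neighbors, length(ord)))]
    d <- sqrt(d2[nb])
    out[tgt[i, 1L], tgt[i, 2L]] <-
      if (config$method == "idw") {
        idw_estimate(d, src_vals[nb], config$idw_power)
      } else {
        ok_estimate(src[nb, , drop = FALSE], src_vals[nb],
                    tgt[i, ], vg)
      }
  }
  res <- climate_raster(raster$spec, out, raster$variable)
  attr(res, "n_unreachable") <- n_unreachable
  res
}

# inverse-distance weighted mean; exact at distance zero
idw_estimate <- function(d, v, power) {
  hit <- d == 0
  if (any(hit)) return(v[which(hit)[1L]])
  w <- 1 / d^power
  sum(w * v) / sum(w)
}

# semivariance under the fitted model
variogram_gamma <- function(h, vg) {
  g <- switch(vg$model,
    exponential = vg$psill * (1 - exp(-h / vg$range)),
    spherical = ifelse(h >= vg$range, vg$psill,
                       vg$psill * (1.5 * h / vg$range -
                                     0.5 * (h / vg$range)^3)))
  ifelse(h == 0, 0, vg$nugget + g)
}

# weighted least squares fit of an isotropic variogram to binned
# empirical semivariances of the source cells (subsampled for large n)
fit_variogram <- function(src, vals, model, max_points = 400L,
                          n_bins = 15L) {
  n <- nrow(src)
  if (n > max_points) {
    keep <- round(seq(1L, n, length.out = max_points))
    src <- src[keep, , drop = FALSE]; vals <- vals[keep]
  }
  n <- nrow(src)
  dmat <- as.matrix(stats::dist(src))
  iu <- upper.tri(dmat)
  h <- dmat[iu]
  g <- 0.5 * (outer(vals, vals, "-")[iu])^2
  hmax <- max(h) / 2
  use <- h > 0 & h <= hmax
  h <- h[use]; g <- g[use]
  if (length(h) < n_bins) {
    # too few pairs to bin: fall back to a pure-nugget-free linear guess
    return(list(model = model, nugget = 0,
                psill = max(stats::var(vals), 1e-12),
                range = max(hmax, 1)))
  }
  bins <- cut(h, breaks = n_bins)
  hb <- tapply(h, bins, mean)
  gb <- tapply(g, bins, mean)
  nb <- tapply(g, bins, length)
  keep <- !is.na(hb)
  hb <- hb[keep]; gb <- gb[keep]; nb <- nb[keep]
  s0 <- max(stats::var(vals), 1e-12)
  obj <- function(p) {
    vgl <- list(model = model, nugget = p[1], psill = p[2], range = p[3])
    sum(nb * (variogram_gamma(hb, vgl) - gb)^2)
  }
  fit <- stats::optim(c(0.1 * s0, s0, hmax / 3), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12, 1e-6),
                      upper = c(2 * s0, 10 * s0, 10 * hmax))
  list(model = model, nugget = fit$par[1], psill = fit$par[2],
       range = fit$par[3])
}

# local ordinary kriging: solve the (k+1)-system with a Lagrange
# multiplier enforcing unit weight sum; exact at distance zero
ok_estimate <- function(nb_coords, nb_vals, tgt_coord, vg) {
  d0 <- sqrt((nb_coords[, 1L] - tgt_coord[1L])^2 +
               (nb_coords[, 2L] - tgt_coord[2L])^2)
  hit <- d0 == 0
  if (any(hit)) return(nb_vals[which(hit)[1L]])
  k <- nrow(nb_coords)
  dmat <- as.matrix(stats::dist(nb_coords))
  A <- rbind(cbind(variogram_gamma(dmat, vg), 1), c(rep(1, k), 0))
  b <- c(variogram_gamma(d0, vg), 1)
  w <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(w)) {
    # singular neighbourhood (e.g. duplicated coordinates): fall back to
    # the IDW estimate, which is defined for any configuration
    return(idw_estimate(d0, nb_vals, 2))
  }
  sum(w[seq_len(k)] * nb_vals)
}

#' Gap-fill every layer of a stack
#'
#' Applies [fill_surface()] with a shared target mask to each layer;
#' used to build the interpolated present (ISP) and LGM (ISL) baselines.
#'
#' @param stack A [bioclim_stack()].
#' @param target_mask Logical matrix (see [shelf_target_mask()]).
#' @param config A [fill_config()].
#' @return The filled [bioclim_stack()].
#' @export
fill_stack <- function(stack, target_mask, config = fill_config()) {
  stopifnot(inherits(stack, "bioclim_stack"))
  bioclim_stack(lapply(stack$layers, fill_surface,
                       target_mask = target_mask, config = config))
}
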
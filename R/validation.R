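#' Pattern correlation between two rasters
#'
#' Pearson's r over the jointly valid cells of two aligned rasters — the
#' standard skill metric for comparing a reconstructed palaeo layer with
#' an independent model snapshot. At least 3 jointly valid cells and
#' nonzero variance on both sides are required.
#'
#' @param a,b Aligned [climate_raster()]s.
#' @return Pearson r in [-1, 1].
#' @export
pattern_correlation <- function(a, b) {
  stopifnot(inherits(a, "climate_raster"), inherits(b, "climate_raster"))
  stop_if_misaligned(a, b)
  keep <- !is.na(a$values) & !is.na(b$values)
  n <- sum(keep)
  if (n < 3L) stop("need at least 3 jointly valid cells, have ", n)
  x <- a$values[keep]; y <- b$values[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance on the joint valid set")
  stats::cor(x, y)
}

#' Quantiles of the absolute difference between two rasters
#'
#' The (default 2.5% and 97.5%) quantiles of |a - b| over jointly valid
#' cells, using the linear-interpolation quantile definition
#' (`stats::quantile` type 7).
#'
#' @param a,b Aligned [climate_raster()]s.
#' @param probs Two probabilities; default `c(0.025, 0.975)`.
#' @return Named numeric vector `c(q_low, q_high)`.
#' @export
abs_diff_quantiles <- function(a, b, probs = c(0.025, 0.975)) {
  stopifnot(inherits(a, "climate_raster"), inherits(b, "climate_raster"),
            length(probs) == 2L, all(probs >= 0 & probs <= 1))
  stop_if_misaligned(a, b)
  keep <- !is.na(a$values) & !is.na(b$values)
  if (!any(keep)) stop("no jointly valid cells")
  q <- stats::quantile(abs(a$values[keep] - b$values[keep]),
                       probs = sort(probs), names = FALSE, type = 7)
  c(q_low = q[1], q_high = q[2])
}

# bilinear interpolation of a coarse grid's values at arbitrary points;
# outside the outermost cell centers the field is edge-clamped
bilinear_at <- function(coarse, px, py) {
  ctr <- cell_centers(coarse$spec)
  xs <- ctr$x                 # ascending
  ys <- rev(ctr$y)            # ascending (south first)
  vals <- coarse$values[rev(seq_len(coarse$spec$nrows)), , drop = FALSE]
  nx <- length(xs); ny <- length(ys)
  ix <- findInterval(px, xs, rightmost.closed = TRUE)
  iy <- findInterval(py, ys, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  if (nx == 1L) ix <- rep(1L, length(px))
  if (ny == 1L) iy <- rep(1L, length(py))
  tx <- (px - xs[ix]) / (xs[pmin(ix + 1L, nx)] - xs[ix])
  ty <- (py - ys[iy]) / (ys[pmin(iy + 1L, ny)] - ys[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  i2 <- pmin(ix + 1L, nx); j2 <- pmin(iy + 1L, ny)
  v11 <- vals[cbind(iy, ix)]; v21 <- vals[cbind(iy, i2)]
  v12 <- vals[cbind(j2, ix)]; v22 <- vals[cbind(j2, i2)]
  (1 - ty) * ((1 - tx) * v11 + tx * v21) +
    ty * ((1 - tx) * v12 + tx * v22)
}

#' Delta-method downscaling of a coarse palaeo snapshot
#'
#' The coarse anomaly (`coarse_paleo - coarse_baseline`) is interpolated
#' to the fine grid's cell centers (bilinear by default, nearest-neighbour
#' optionally) and added to the fine-resolution observed baseline. Output
#' is missing wherever the fine baseline is missing or the coarse anomaly
#' is missing at the contributing cells.
#'
#' @param coarse_paleo,coarse_baseline Aligned coarse [climate_raster()]s.
#' @param fine_baseline Fine-resolution baseline [climate_raster()]; its
#'   cell centers must fall inside the coarse extent.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A [climate_raster()] on the fine grid.
#' @export
delta_downscale <- function(coarse_paleo, coarse_baseline, fine_baseline,
                            method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(coarse_paleo, "climate_raster"),
            inherits(coarse_baseline, "climate_raster"),
            inherits(fine_baseline, "climate_raster"))
  stop_if_misaligned(coarse_paleo, coarse_baseline, "coarse grids")
  cs <- coarse_paleo$spec; fs <- fine_baseline$spec
  cxmax <- cs$xllcorner + cs$ncols * cs$cellsize
  cymax <- cs$yllcorner + cs$nrows * cs$cellsize
  fxmax <- fs$xllcorner + fs$ncols * fs$cellsize
  fymax <- fs$yllcorner + fs$nrows * fs$cellsize
  if (fs$xllcorner >= cxmax || fxmax <= cs$xllcorner ||
      fs$yllcorner >= cymax || fymax <= cs$yllcorner)
    stop("fine and coarse extents do not overlap")

  anom <- climate_raster(cs, coarse_paleo$values - coarse_baseline$values,
                         coarse_paleo$variable)
  ctr <- cell_centers(fs)
  px <- rep(ctr$x, each = fs$nrows)      # column-major over (row, col)
  py <- rep(ctr$y, times = fs$ncols)
  a <- if (method == "bilinear") {
    bilinear_at(anom, px, py)
  } else {
    cc <- cell_centers(cs)
    ci <- pmin(pmax(round((py - cc$y[cs$nrows]) / cs$cellsize) + 1L, 1L),
               cs$nrows)
    cj <- pmin(pmax(round((px - cc$x[1L]) / cs$cellsize) + 1L, 1L),
               cs$ncols)
    anom$values[cbind(cs$nrows - ci + 1L, cj)]
  }
  av <- matrix(a, nrow = fs$nrows, ncol = fs$ncols)
  climate_raster(fs, fine_baseline$values + av, fine_baseline$variable)
}

#' Compare two stacks variable by variable
#'
#' For every shared variable, Pearson pattern correlation, the 2.5% and
#' 97.5% absolute-difference quantiles, and the number of jointly valid
#' cells — the layout of a standard palaeo-layer validation table.
#'
#' @param a,b [bioclim_stack()]s on aligned grids.
#' @param report Optional CSV path; if given the table is also written
#'   with columns `variable, pearson_r, q025, q975, n_cells`.
#' @param probs Quantile probabilities; default `c(0.025, 0.975)`.
#' @return Data frame with one row per shared variable.
#' @export
compare_stacks <- function(a, b, report = NULL, probs = c(0.025, 0.975)) {
  stopifnot(inherits(a, "bioclim_stack"), inherits(b, "bioclim_stack"))
  vars <- intersect(names(a$layers), names(b$layers))
  if (length(vars) == 0L) stop("stacks share no variables")
  rows <- lapply(vars, function(v) {
    la <- a$layers[[v]]; lb <- b$layers[[v]]
    keep <- !is.na(la$values) & !is.na(lb$values)
    r <- pattern_correlation(la, lb)
    q <- abs_diff_quantiles(la, lb, probs)
    data.frame(variable = v, pearson_r = r,
               q025 = q[["q_low"]], q975 = q[["q_high"]],
               n_cells = sum(keep))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(report)) {
    dir.create(dirname(report), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, report, row.names = FALSE)
  }
  out
}
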
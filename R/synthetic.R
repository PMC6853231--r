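#' Configuration for the synthetic test world
#'
#' The generator emulates the statistical structure the anomaly method
#' assumes, without any downloads: spatially autocorrelated bioclim
#' surfaces, an LGM stack that is a cooled (temperature ids) and drier
#' (precipitation ids) perturbation of the present stack, a DEM with a
#' continental core, a gently sloping shelf and deep ocean — optionally
#' with a walled depression below sea level — and a sawtooth
#' temperature / sea-level curve over the 20-5,400 kyr lattice.
#'
#' @param ncols,nrows Grid dimensions (>= 8 each); defaults 60 x 40.
#' @param cellsize Degrees per cell; default 1.
#' @param xllcorner,yllcorner Lower-left corner; defaults place the grid
#'   roughly astride the equator.
#' @param seed Integer seed; one world per seed, reproducible bit for bit.
#' @param autocorr_cells Correlation length of the random fields in cells
#'   (>= 1); default 5.
#' @param lgm_cooling_c Mean LGM cooling applied to temperature ids,
#'   degrees C; default 4.44, the canonical global present-LGM contrast.
#' @param lgm_drying_frac Fractional LGM precipitation reduction in
#'   [0, 1); default 0.2.
#' @param shelf_width_cells Width of the sub-sea-level shelf ring; default 4.
#' @param depression Add one landlocked below-sea-level basin; default TRUE.
#' @param vars Variable ids to generate; default all 19.
#' @return A `world_config` list.
#' @export
world_config <- function(ncols = 60L, nrows = 40L, cellsize = 1,
                         xllcorner = -30, yllcorner = -20, seed = 1L,
                         autocorr_cells = 5L, lgm_cooling_c = 4.44,
                         lgm_drying_frac = 0.2, shelf_width_cells = 4L,
                         depression = TRUE, vars = bioclim_vars()) {
  if (ncols < 8L || nrows < 8L) stop("world must be at least 8 x 8")
  if (autocorr_cells < 1L) stop("autocorr_cells must be >= 1")
  if (lgm_drying_frac < 0 || lgm_drying_frac >= 1)
    stop("lgm_drying_frac must lie in [0, 1)")
  structure(list(ncols = as.integer(ncols), nrows = as.integer(nrows),
                 cellsize = cellsize, xllcorner = xllcorner,
                 yllcorner = yllcorner, seed = as.integer(seed),
                 autocorr_cells = as.integer(autocorr_cells),
                 lgm_cooling_c = lgm_cooling_c,
                 lgm_drying_frac = lgm_drying_frac,
                 shelf_width_cells = as.integer(shelf_width_cells),
                 depression = isTRUE(depression), vars = vars),
            class = "world_config")
}

# run code with a private RNG stream, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# white noise convolved with a separable box kernel of width w (with
# edge renormalisation), giving fields with correlation length ~ w cells
smooth_field <- function(nrows, ncols, w) {
  z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  if (w <= 1L) return(z)
  k <- rep(1, 2L * w %/% 2L + 1L)
  sm1 <- function(x) {
    n <- length(x)
    num <- stats::convolve(x, k, type = "open")
    den <- stats::convolve(rep(1, n), k, type = "open")
    off <- (length(k) - 1L) %/% 2L
    (num / den)[(off + 1L):(off + n)]
  }
  z <- t(apply(z, 1L, sm1))
  z <- apply(z, 2L, sm1)
  # restore unit variance so amplitudes stay comparable across widths
  (z - mean(z)) / stats::sd(z)
}

#' Sawtooth temperature / sea-level curve on the canonical lattice
#'
#' A piecewise-linear sawtooth over the 539 ages of
#' `build_timeline(20, 5400, 10)`, oscillating between the endpoints of
#' `ts_range`; sea level co-varies linearly with Ts so that the
#' `sealevel_range` endpoints are attained exactly at the Ts extremes —
#' the qualitative shape of glacial cycles in the isotope-derived record.
#'
#' @param n_cycles Number of sawtooth cycles (>= 1); default 10.
#' @param ts_range Global temperature range `(min, max)`, degrees C;
#'   default the canonical anchors `c(9.46, 13.90)`.
#' @param sealevel_range Sea-level range `(min, max)` in metres attained
#'   at the Ts extremes; default `c(-125, 0)`.
#' @param ts_present_c,ts_lgm_c Anchor temperatures; defaults 13.90 / 9.46.
#' @param ages Period ages; default the canonical 539-age lattice.
#' @return A [temperature_curve()].
#' @export
make_curve <- function(n_cycles = 10L, ts_range = c(9.46, 13.90),
                       sealevel_range = c(-125, 0),
                       ts_present_c = 13.90, ts_lgm_c = 9.46,
                       ages = build_timeline(20, 5400, 10)) {
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (ts_range[1] >= ts_range[2]) stop("ts_range must be increasing")
  n <- length(ages)
  phase <- (seq_len(n) - 1L) / (n - 1L) * n_cycles
  saw <- 1 - abs(2 * (phase %% 1) - 1)      # triangle wave in [0, 1]
  # rescale so the attained extremes hit the range endpoints exactly even
  # when cycle peaks fall between lattice ages
  saw <- (saw - min(saw)) / (max(saw) - min(saw))
  ts <- ts_range[1] + saw * (ts_range[2] - ts_range[1])
  # linear coupling: coldest Ts -> lowest stand, warmest -> highest
  sl <- sealevel_range[1] + saw * (sealevel_range[2] - sealevel_range[1])
  temperature_curve(ages, ts, sl, ts_present_c = ts_present_c,
                    ts_lgm_c = ts_lgm_c)
}

# DEM: radial continental core above sea level, shelf ring in (-120, 0],
# deep ocean below -120 m; optionally a small walled basin in the interior
make_dem <- function(cfg) {
  nr <- cfg$nrows; nc <- cfg$ncols
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # elliptical distance from grid center, 1 at the reference coast
  dy <- (ri - (nr + 1) / 2) / (nr * 0.33)
  dx <- (ci - (nc + 1) / 2) / (nc * 0.33)
  r <- sqrt(dx^2 + dy^2)
  shelf_r <- cfg$shelf_width_cells / (min(nr, nc) * 0.33)
  elev <- matrix(NA_real_, nr, nc)
  inland <- r <= 1
  elev[inland] <- 800 * (1 - r[inland])^1.2 + 10
  on_shelf <- r > 1 & r <= 1 + shelf_r
  elev[on_shelf] <- -118 * (r[on_shelf] - 1) / shelf_r
  deep <- r > 1 + shelf_r
  elev[deep] <- -120 - 3500 * pmin((r[deep] - 1 - shelf_r), 1)
  if (cfg$depression) {
    # walled basin: a 3x3 floor at -30 m deep inside the continent, where
    # the surrounding terrain is far above sea level at any grid size
    br <- round(nr / 2 + nr * 0.08); bc <- round(nc / 2 + nc * 0.1)
    elev[(br - 1):(br + 1), (bc - 1):(bc + 1)] <- -30
  }
  elev
}

#' Generate a complete synthetic world
#'
#' Deterministic from `config$seed` (a private RNG stream; global RNG
#' state is untouched). Present-day layers exist on present land
#' (DEM > 0 m) and are missing at sea, mirroring observed climatologies;
#' the LGM stack is `present - lgm_cooling_c` plus a mild
#' latitude-dependent term for temperature ids and
#' `present * (1 - lgm_drying_frac)` for precipitation ids. Simple
#' cross-variable construction rules keep ids realistic (e.g.
#' `bio7 = bio5 - bio6` at generation time).
#'
#' @param config A [world_config()].
#' @return List with `present` and `lgm` [bioclim_stack()]s, `dem`
#'   ([climate_raster()], metres) and `curve` ([temperature_curve()]).
#' @export
make_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  spec <- grid_spec(config$ncols, config$nrows, config$xllcorner,
                    config$yllcorner, config$cellsize)
  with_local_seed(config$seed, {
    dem_vals <- make_dem(config)
    dem <- climate_raster(spec, dem_vals, "dem")
    land <- dem_vals > 0
    lat <- matrix(cell_centers(spec)$y, config$nrows, config$ncols)
    latn <- (lat - mean(lat)) / max(abs(lat - mean(lat)))  # in [-1, 1]

    base_field <- function(center, amplitude, lat_slope = 0) {
      f <- smooth_field(config$nrows, config$ncols, config$autocorr_cells)
      center + amplitude * f + lat_slope * latn
    }
    temp_ids <- setdiff(intersect(config$vars, paste0("bio", 1:11)), NULL)
    prec_ids <- intersect(config$vars, precipitation_vars())

    pres <- list()
    # temperature ids (degrees C): means decline poleward
    centers_t <- c(bio1 = 18, bio2 = 10, bio3 = 45, bio4 = 60, bio5 = 28,
                   bio6 = 6, bio7 = 22, bio8 = 20, bio9 = 15, bio10 = 24,
                   bio11 = 10)
    for (v in temp_ids)
      pres[[v]] <- base_field(centers_t[[v]], 2.5, lat_slope = -6)
    # precipitation ids (mm): strictly positive
    centers_p <- c(bio12 = 1200, bio13 = 220, bio14 = 25, bio15 = 55,
                   bio16 = 520, bio17 = 110, bio18 = 340, bio19 = 260)
    for (v in prec_ids)
      pres[[v]] <- pmax(base_field(centers_p[[v]], centers_p[[v]] * 0.25),
                        0)
    # cross-variable consistency at generation time
    if (all(c("bio5", "bio6", "bio7") %in% names(pres)))
      pres$bio7 <- pres$bio5 - pres$bio6

    # LGM perturbation: cooler (with a high-latitude amplification term)
    # for temperature ids, drier for precipitation ids, plus spatially
    # structured noise so the delta layers are non-trivial. All terms
    # scale with the perturbation magnitude, so zero cooling and drying
    # reproduce the present stack exactly.
    lgm <- list()
    for (v in names(pres)) {
      eps <- smooth_field(config$nrows, config$ncols,
                          config$autocorr_cells)
      if (v %in% temp_ids) {
        lgm[[v]] <- pres[[v]] -
          config$lgm_cooling_c * (1 + 0.34 * abs(latn)) +
          0.07 * config$lgm_cooling_c * eps
      } else {
        lgm[[v]] <- pmax(pres[[v]] * (1 - config$lgm_drying_frac) +
                           config$lgm_drying_frac * 0.1 *
                             centers_p[[v]] * eps, 0)
      }
    }
    if (all(c("bio5", "bio6", "bio7") %in% names(lgm)))
      lgm$bio7 <- lgm$bio5 - lgm$bio6

    to_stack <- function(lst) {
      bioclim_stack(lapply(names(lst), function(v) {
        m <- lst[[v]]
        m[!land] <- NA_real_
        climate_raster(spec, m, v)
      }))
    }
    list(present = to_stack(pres), lgm = to_stack(lgm), dem = dem,
         curve = make_curve())
  })
}
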
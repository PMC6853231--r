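#' Construct a temperature / sea-level curve
#'
#' The curve carries one row per 10-kyr time period (age in kyr BP, global
#' mean surface temperature Ts in degrees C, eustatic sea level in metres
#' relative to present, negative = lower) plus the two anchor constants
#' that define the anomaly scale factor: the present-day and LGM global
#' mean temperatures. The canonical anchors are Ts_LGM = 9.46 degrees C
#' with the present 4.44 degrees C warmer (13.90 degrees C).
#'
#' @param age_kyr Strictly positive ages, kyr before present; must be unique.
#' @param ts_c Global mean surface temperature per period, degrees C.
#' @param sea_level_m Eustatic sea level per period, metres (negative =
#'   below present).
#' @param ts_present_c,ts_lgm_c Anchor temperatures, degrees C; the present
#'   anchor must exceed the LGM anchor.
#' @return A `temperature_curve`: a data frame with columns `index`
#'   (age / 10, the T-number: T2 = 20 kyr, T3 = 30 kyr, ...), `age_kyr`,
#'   `ts_c`, `sea_level_m`, sorted by age, with anchor attributes
#'   `ts_present_c` and `ts_lgm_c`.
#' @export
temperature_curve <- function(age_kyr, ts_c, sea_level_m,
                              ts_present_c = 13.90, ts_lgm_c = 9.46) {
  n <- length(age_kyr)
  if (n < 1L) stop("curve needs at least one period")
  if (length(ts_c) != n || length(sea_level_m) != n)
    stop("age_kyr, ts_c, sea_level_m must have equal length")
  if (any(!is.finite(age_kyr)) || any(!is.finite(ts_c)) ||
      any(!is.finite(sea_level_m)))
    stop("curve values must be finite")
  if (any(age_kyr <= 0)) stop("ages must be positive (kyr BP)")
  if (anyDuplicated(age_kyr)) stop("duplicate ages in curve")
  if (!is.finite(ts_present_c) || !is.finite(ts_lgm_c) ||
      ts_present_c <= ts_lgm_c)
    stop("ts_present_c must exceed ts_lgm_c")
  ord <- order(age_kyr)
  out <- data.frame(index = age_kyr[ord] / 10,
                    age_kyr = age_kyr[ord],
                    ts_c = ts_c[ord],
                    sea_level_m = sea_level_m[ord])
  attr(out, "ts_present_c") <- as.numeric(ts_present_c)
  attr(out, "ts_lgm_c") <- as.numeric(ts_lgm_c)
  class(out) <- c("temperature_curve", "data.frame")
  out
}

#' Anchor temperatures of a curve
#' @param curve A [temperature_curve()].
#' @return Named numeric vector with `ts_present_c` and `ts_lgm_c`.
#' @export
curve_anchors <- function(curve) {
  c(ts_present_c = attr(curve, "ts_present_c"),
    ts_lgm_c = attr(curve, "ts_lgm_c"))
}

#' Load a temperature / sea-level curve from a CSV file
#'
#' The file must have a header `age_kyr,ts_c,sea_level_m`. Anchors may be
#' stored as comment lines before the header (`# ts_present_c: 13.90`,
#' `# ts_lgm_c: 9.46`); explicit arguments override file metadata, and the
#' canonical defaults apply when neither is given.
#'
#' @param path CSV path.
#' @param ts_present_c,ts_lgm_c Optional anchor overrides, degrees C.
#' @return A [temperature_curve()].
#' @export
load_curve <- function(path, ts_present_c = NULL, ts_lgm_c = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines, value = TRUE)
  meta_val <- function(key) {
    m <- grep(paste0(key, "\\s*[:=]"), meta, value = TRUE)
    if (length(m) == 0L) return(NULL)
    as.numeric(sub(paste0(".*", key, "\\s*[:=]\\s*"), "", m[1]))
  }
  if (is.null(ts_present_c))
    ts_present_c <- meta_val("ts_present_c") %||% 13.90
  if (is.null(ts_lgm_c))
    ts_lgm_c <- meta_val("ts_lgm_c") %||% 9.46
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("age_kyr", "ts_c", "sea_level_m")
  if (!all(need %in% names(tab)))
    stop("curve file must have columns ", paste(need, collapse = ", "))
  temperature_curve(tab$age_kyr, tab$ts_c, tab$sea_level_m,
                    ts_present_c = ts_present_c, ts_lgm_c = ts_lgm_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a curve to CSV (anchors as comment metadata)
#'
#' @param curve A [temperature_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  an <- curve_anchors(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ts_present_c: %.6g", an[["ts_present_c"]]),
               sprintf("# ts_lgm_c: %.6g", an[["ts_lgm_c"]]),
               "age_kyr,ts_c,sea_level_m"), con)
  writeLines(sprintf("%.10g,%.10g,%.10g",
                     curve$age_kyr, curve$ts_c, curve$sea_level_m), con)
  invisible(path)
}

#' The 10-kyr period lattice
#'
#' Ages `start, start + step, ..., end` inclusive. The canonical lattice
#' spans the LGM (20 kyr BP) to the early Pliocene (5,400 kyr BP) in 10-kyr
#' steps, giving 539 periods.
#'
#' @param start_kyr,end_kyr First and last age, kyr BP; `start <= end`.
#' @param step_kyr Positive step, kyr; default 10.
#' @return Numeric vector of ages.
#' @export
build_timeline <- function(start_kyr = 20, end_kyr = 5400, step_kyr = 10) {
  if (!is.finite(step_kyr) || step_kyr <= 0) stop("step must be positive")
  if (start_kyr > end_kyr) stop("start must not exceed end")
  seq(start_kyr, end_kyr, by = step_kyr)
}

#' The anomaly scale factor for a period
#'
#' The dimensionless ratio `(Ts_T - Ts_LGM) / (Ts_present - Ts_LGM)` that
#' scales the LGM anomaly layer for a period with global temperature
#' `ts_t`. Exactly 0 at the LGM anchor, exactly 1 at the present anchor;
#' may exceed 1 for periods warmer than present (e.g. the Pliocene) or be
#' negative for periods colder than the LGM.
#'
#' @param ts_t Global mean surface temperature of the period, degrees C
#'   (vectorised).
#' @param curve A [temperature_curve()] supplying the anchors.
#' @return Numeric vector of scale factors.
#' @export
scale_factor <- function(ts_t, curve) {
  an <- curve_anchors(curve)
  (ts_t - an[["ts_lgm_c"]]) / (an[["ts_present_c"]] - an[["ts_lgm_c"]])
}

#' Resample a curve onto a set of ages
#'
#' Interpolates Ts and sea level onto new ages, linearly by default
#' (nearest-neighbour available); used to put an off-lattice source curve
#' onto the 10-kyr lattice. Requested ages must lie inside the curve's age
#' span (no extrapolation).
#'
#' @param curve A [temperature_curve()].
#' @param ages Target ages, kyr BP.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A [temperature_curve()] on `ages` with the same anchors.
#' @export
resample_curve <- function(curve, ages, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (min(ages) < min(curve$age_kyr) || max(ages) > max(curve$age_kyr))
    stop("requested ages fall outside the curve's span")
  ts <- stats::approx(curve$age_kyr, curve$ts_c, xout = ages,
                      ties = "ordered")$y
  sl <- stats::approx(curve$age_kyr, curve$sea_level_m, xout = ages,
                      ties = "ordered")$y
  if (method == "nearest") {
    idx <- vapply(ages, function(a) which.min(abs(curve$age_kyr - a)),
                  integer(1))
    ts <- curve$ts_c[idx]; sl <- curve$sea_level_m[idx]
  }
  an <- curve_anchors(curve)
  temperature_curve(ages, ts, sl,
                    ts_present_c = an[["ts_present_c"]],
                    ts_lgm_c = an[["ts_lgm_c"]])
}
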
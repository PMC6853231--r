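---
title: "Generating anomaly-scaled palaeo-bioclim layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating anomaly-scaled palaeo-bioclim layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodelta)
```

## The method

Ecological niche models projected through the Plio-Pleistocene need climate
layers at far higher temporal resolution than general circulation model
(GCM) snapshots provide. `paleodelta` fills that gap with the anomaly
(Delta) method, which assumes that the *spatial pattern* of glacial-
interglacial climate change is well captured by the contrast between two
well-constrained states — the present and the Last Glacial Maximum (LGM,
taken as 20 kyr BP) — and that the *amplitude* of that pattern through time
follows the global mean surface temperature curve derived from the benthic
oxygen-isotope record.

For each bioclim variable $b$ and time period $T$:

1. **Shelf gap-filling.** Present-day and LGM layers only exist on the
   modern land surface, but glacial coastlines extend onto the continental
   shelf. Both layers are extended over all cells that are submerged today
   yet exposed at the lowest sea-level stand of the series, giving the
   interpolated surfaces ISP and ISL. The interpolators are exact and
   local (inverse-distance weighting by default, local ordinary kriging
   optionally), which honours the assumption of spatial correlation
   between coastal and near-offshore climate without inventing values in
   the open ocean.
2. **Anomaly.** $\Delta_b = \mathrm{ISP}_b - \mathrm{ISL}_b$, cellwise,
   valid where both operands are.
3. **Temperature scaling.** Each period's anomaly fraction is
   $f_T = (T\!s_T - T\!s_{\mathrm{LGM}}) / (T\!s_{\mathrm{present}} -
   T\!s_{\mathrm{LGM}})$, with anchors $T\!s_{\mathrm{LGM}} = 9.46$ °C and a
   present 4.44 °C warmer. $f_T$ is exactly 0 at the LGM, exactly 1 at
   present, above 1 for periods warmer than present (e.g. the Pliocene)
   and below 0 for periods colder than the LGM.
4. **Calibration.** $b_T = \mathrm{ISL}_b + f_T \, \Delta_b$. The glacial
   baseline, not the raw LGM layer, carries the addition so that shelf
   cells receive values.
5. **Coastlines.** The period's layer is clipped with a land mask obtained
   by reclassifying a DEM at the period's eustatic sea level: cells above
   the stand are land; cells at or below it are sea only if flood-fill
   connected to the ocean; below-level cells without such a connection
   (e.g. the Qattara Depression at present sea level) are *landlocked
   missing data*, not lakes.

Validation utilities compute the conventional skill metrics between a
generated stack and an independent GCM snapshot — Pearson pattern
correlation and the 2.5 %/97.5 % quantiles of the absolute difference over
jointly valid cells — plus Delta-method downscaling of a coarse snapshot
onto a fine baseline (bilinear anomaly transfer by default).

## A worked run

```{r, eval = FALSE}
w <- make_world(world_config(seed = 1))
res <- run_generate(run_config(
  present = w$present, lgm = w$lgm, dem = w$dem, curve = w$curve,
  out_dir = "out", periods = build_timeline(20, 120, 10)))
head(res)
```

Each period directory `out/<age>kyr/` holds one ESRI ASCII grid per
variable, and `out/run_log.jsonl` one JSON record per period (age, Ts,
anomaly factor, sea level, per-variable clamp and missing-cell counts).

## Parameters that matter

* **Anchors** `ts_present_c` / `ts_lgm_c` (°C; defaults 13.90 / 9.46).
  They define the denominator of $f_T$; a curve is rejected unless the
  present anchor exceeds the LGM anchor. They are curve metadata rather
  than rows, so a curve need not contain an exact 20-kyr entry.
* **Fill settings** (`fill_config()`): `idw_power` (2), `max_neighbors`
  (12), `search_radius_cells` (25). The radius cap keeps mid-ocean cells
  missing instead of receiving long-range extrapolations; neighbour ties
  at equal distance are broken by (row, column) order so outputs are
  reproducible. Distances are Euclidean in cell units — adequate for
  shelf-scale neighbourhoods, increasingly distorted towards the poles.
* **Clamping.** Additive anomalies can drive precipitation negative;
  `bio12`–`bio19` are clamped at zero by default (`clamp = FALSE` turns
  this off) and every clamped cell is counted in the run log. Temperature
  ids are never clamped.
* **Connectivity** of the ocean flood fill (8 by default, so diagonal
  straits count as water; 4 available). Border cells below the stand seed
  the ocean; regional crops whose borders are land can pass an explicit
  `ocean_seed`.
* **Latitude cut** `south_cut_deg` (−60°) masks Antarctica-like land.

## Design choices where the method is genuinely open

* **Interpolator.** Empirical Bayesian kriging implementations are tied to
  proprietary GIS stacks and underdocumented parameters; this package
  offers two transparent exact interpolators instead and treats the choice
  as a measurable one — the validation module quantifies its consequences.
  IDW is the default because it is parameter-light and order-independent;
  ordinary kriging (exponential or spherical variogram fitted by weighted
  least squares to binned empirical semivariances) is available where a
  geostatistical fill is preferred.
* **Baseline of the calibration step.** The anomaly is added to ISL rather
  than the raw LGM layer: offshore shelf cells exist only in ISL, and on
  the shared valid set the two are identical because the fill is exact.
* **Anomaly form.** The anomaly is additive for all 19 variables,
  including precipitation; no ratio-based variant is applied. Clamping
  (with logging) addresses the resulting negative-precipitation cells.
* **Cross-variable consistency.** Each variable is scaled independently
  with the same temperature-derived factor; derived identities such as
  `bio7 = bio5 - bio6` are *not* re-enforced after scaling. Because the
  transformation is affine with a shared factor, identities that hold in
  both input stacks are in fact preserved before clamping; clamping can
  break them, which is reported, not repaired.
* **Curve resampling.** Source curves that are not on the 10-kyr lattice
  are interpolated linearly by default (`resample_curve()`), with
  nearest-neighbour as an alternative.
* **Quantile definition.** Linear interpolation between order statistics
  (`stats::quantile` type 7); comparisons use pairwise-complete cells and
  always report `n_cells` so the masking convention is auditable.
* **Registration.** Corner registration is canonical; `xllcenter` headers
  are converted on read. Missing `NODATA_value` defaults to −9999. Grids
  are stored north-first, matching file order. Alignment tolerance is
  1e-9 degrees — wide enough to absorb decimal printing jitter, narrow
  enough to catch real misalignment.

## What the synthetic world does and does not emulate

`make_world()` builds, deterministically from one seed on a private RNG
stream: smooth random fields (white noise convolved with a box kernel of
width `autocorr_cells`) for the 19 variables; an LGM stack that is cooler
by `lgm_cooling_c` (default 4.44 °C, amplified up to 34 % towards high
latitudes) and drier by `lgm_drying_frac` (default 20 %), with
perturbation noise that scales with those magnitudes so zero parameters
reproduce the present stack exactly; an elliptical continent with a shelf
ring in (−120, 0] m, deep ocean and an optional walled −30 m basin; and a
sawtooth curve over the 539-period lattice whose sea level co-varies
linearly with Ts between −125 m and 0 m.

It emulates spatial autocorrelation, the cooler/drier LGM contract, the
shelf/coastline geometry and glacial cyclicity — and nothing else. Passing
tests therefore demonstrate the correctness of the algebra, the I/O, the
masks and the scaling on data with the method's assumed structure; they
say nothing about how faithful any real GCM anomaly is, about
orography-driven precipitation patterns, ice sheets, isostasy, or
non-stationary land configurations (all outside the method).

Default problem sizes — a 60 × 40 grid for end-to-end runs and full
539-period generation, smaller grids for unit oracles — were chosen as the
smallest worlds that exercise every code path (shelf, depression, both
mask states, all 19 variables) while keeping the whole suite fast on a
laptop.

## Numerical notes and limitations

* The anchor identities $f(T\!s_{\mathrm{LGM}}) = 0$ and
  $f(T\!s_{\mathrm{present}}) = 1$ hold exactly in floating point because
  numerator and denominator are computed from the same expressions.
* ASCII round trips preserve values to half the last printed digit
  (`decimals`, default 4) and the missing pattern exactly; the printed
  precision of distributed files is a user decision, not guessed.
* Cells exactly at sea level are sea (strict `elevation > level` defines
  land); ties are measure-zero in real DEMs.
* Kriging neighbourhoods with singular systems (duplicate coordinates)
  fall back to the IDW estimate for that cell.
* `cell_area_km2()` is the small-cell cosine approximation with a
  configurable kilometres-per-degree constant (default 111.6, which gives
  the conventional 21.62 km² for a 2.5′ cell at the equator).
* Everything is geographic latitude/longitude on one shared grid; there is
  no reprojection, resampling between resolutions (other than the bilinear
  anomaly transfer in validation), or NetCDF support.
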
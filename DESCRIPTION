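Package: paleodelta
Title: Anomaly-Scaled Palaeo-Bioclim Layers with Sea-Level Coastlines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates high-temporal-resolution palaeo-bioclim layers by the
    anomaly (Delta) method: present-day and Last Glacial Maximum bioclim
    surfaces are gap-filled over the continental shelf, their cellwise
    difference is scaled through a Plio-Pleistocene global mean temperature
    curve, added back onto the glacial baseline, and clipped with
    sea-level-dependent palaeo-coastlines derived from a DEM (landlocked
    depressions below sea level become missing data). Includes ESRI ASCII
    grid I/O, inverse-distance and ordinary-kriging gap filling, flood-fill
    coastline reclassification, raster pattern-correlation and
    absolute-difference validation statistics, Delta-method downscaling of
    coarse model snapshots, a deterministic synthetic-world generator for
    download-free testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
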
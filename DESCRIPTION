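Package: canopyflux
Title: Canopy Gap Dynamics from Repeat Canopy Height Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects canopy gaps in repeat airborne-laser-scanning canopy
    height models, classifies per-pixel change into five dynamic classes
    (gap formation, canopy disturbance, gap persistence, gap closure,
    intact canopy), aggregates per-hectare gain/loss/net rates of canopy
    height and volume, derives topographic covariates (elevation, slope,
    topographic wetness index) from a digital terrain model, and relates
    dynamics to topography and canopy structure with spatially buffered
    leave-one-out cross-validated regressions. Includes a synthetic
    landscape simulator with per-pixel truth labels for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
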
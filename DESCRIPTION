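Package: arcuatefit
Title: Retinal Nerve Fiber Bundle Trajectory Modelling and Arcuate Defect
    Fitting for OCT RNFL Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models retinal nerve fiber bundle trajectories around the optic
    nerve head with a modified Jansonius-type polar trajectory model, extracts
    the borders of arcuate-shaped defects from OCT retinal nerve fiber layer
    (RNFL) probability maps, fits trajectories to those borders by normalized
    root-mean-square grid search over the model's curvature parameter and
    initial angular position, and maps best-fit positions onto the
    circumpapillary RNFL (TSNIT) thickness profile to quantify the abnormal
    angular region. Includes a seeded synthetic-data generator producing
    georeferenced probability maps with model-derived arcuate defects and
    matching circumpapillary profiles, plus a small command-line interface
    and static report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    png,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
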
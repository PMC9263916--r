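Package: uavph
Title: Plot-Level Plant Height from UAV Photogrammetry Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts plot-level plant height of row crops from digital
    surface models (DSMs) produced by UAV structure-from-motion
    photogrammetry. Implements three ground-altitude strategies: off-season
    DSM differencing, within-plot soil/apex percentiles, and a polynomial
    digital terrain model interpolated from bare ground sampled around the
    field. Includes percentile zonal statistics over rectangular regions of
    interest, least-squares polynomial surface fitting with degree
    selection, linear calibration of photogrammetric height against
    ruler-measured height, and a cross-validation scheme in which
    validation samples come from both a different spatial group and a
    different flight than the training samples. A synthetic scene generator
    emulates the statistical structure of photogrammetric rasters (tilted
    terrain, central doming distortion, per-flight vertical datum offsets,
    row-crop canopies with hidden or visible soil, and small high-value
    noise blobs) so that every stage of the pipeline can be exercised and
    tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
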
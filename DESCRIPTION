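Package: understoRy
Title: Understory Vegetation Density from Terrestrial and Airborne Laser Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and maps forest understory vegetation density from
    lidar point clouds. Terrestrial laser scans of field plots are voxelized
    (0.5 x 0.5 x 0.25 m cells, vegetated when holding at least five points)
    into stratified Plant Density Index (PDI) profiles; airborne laser
    scanning (ALS) first returns yield seventeen plot-level height and
    density metrics; correlation-screened linear models with leave-one-out
    cross-validation link the two; and fitted models are applied wall-to-wall
    on a 25 m grid to produce understory density rasters. A synthetic forest
    scene simulator with known ground truth supports end-to-end testing and
    parameter-recovery experiments without field data. Includes a minimal
    LAS 1.2 reader/writer and ESRI ASCII grid raster output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
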
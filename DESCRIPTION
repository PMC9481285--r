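Package: seedling3d
Title: Point-Cloud Phenotyping of Maize Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts phenotypic traits of maize seedlings from colored 3D
    point clouds reconstructed by multi-view photogrammetry. Provides the full
    processing chain: Euclidean-cluster background removal, RGB
    color-threshold noise filtering, voxel-grid downsampling, checkerboard
    scale calibration, growth-axis alignment, plant and stem height
    measurement (RANSAC line fitting of the stalk), leaf length, width and
    relative-area measurement, and region-growing stem/leaf segmentation
    driven by surface normals and curvature. A synthetic maize-scene
    generator with exact ground truth supports offline validation, and an
    evaluation module computes absolute/relative error tables and
    agreement statistics against manual measurements. Point clouds are plain
    tibbles (one row per point) so every stage composes with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RANN,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
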
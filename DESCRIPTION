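Package: tlstation
Title: Processing and Forest-Dynamics Analysis for a Permanent Terrestrial
    Laser Scanning Station
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for processing point-cloud time series from a fixed,
    automated terrestrial laser scanning (TLS) station monitoring a forest
    scene. Enriches raw scanner-frame point clouds with spherical coordinates
    and angular raster indices, reads and writes ASPRS LAS 1.4 files with
    user-defined extra-byte attributes, rasterizes scans into per-return
    range/reflectance/deviation images, gates scans on calm-weather criteria,
    and runs the station's forest-dynamics analyses: voxel-based crown
    densification (leaf sprout detection), RANSAC cylinder fitting for stem
    diameter (DBH) time series, and nearest-neighbour cluster tracking of
    sub-decimetre circadian branch movements. A ground-truthed synthetic
    scene simulator (parametric trees sampled on the scanner's angular grid,
    with multi-return foliage, sprouting and diurnal motion) makes every
    analysis testable without a scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
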
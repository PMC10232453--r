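Package: vhiopt
Title: Optimally Weighted Vegetation Health Index for Drought Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate an improved Vegetation Health Index
    (VHI) for vegetation drought monitoring. Computes the Vegetation Condition
    Index (VCI) and Thermal Condition Index (TCI) from NDVI and land surface
    temperature stacks, estimates per pixel the optimal VCI/TCI contribution
    weight by maximizing Pearson correlation of the weighted VHI with a
    reference meteorological drought index (such as the self-calibrating
    Palmer Drought Severity Index), classifies drought severity, scores
    recorded drought events to measure detection efficiency, and maps
    Theil-Sen slopes with Mann-Kendall significance. Includes lightweight
    single-band GeoTIFF input/output for gridded index time series and a
    synthetic-scene generator with known mixing weights for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
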
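Package: rseimap
Title: Remote Sensing Ecological Index Mapping with Trend and
    Change-Point Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the Remote Sensing Ecological Index (RSEI) from
    multiband surface-reflectance and thermal raster time series.  Builds
    seasonal (September-March) annual composites with quality-bit masking
    and nearest-neighbor resampling to a common geographic grid, derives
    the four RSEI indicators (NDBSI dryness, NDVI greenness, land surface
    temperature heat, tasseled-cap wetness), extracts the first principal
    component into a normalized [0,1] index with a five-class ecological
    quality scheme, and maps per-pixel Theil-Sen slopes, Mann-Kendall
    trend significance and Pettitt change points across the annual
    series.  Includes a synthetic MODIS-like scene generator with known
    land-cover structure, trends and change points, a lightweight GeoTIFF
    reader/writer, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
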
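Package: saviopt
Title: Calibrating the SAVI Soil Adjustment Factor for Leaf Area Index
    Estimation in Dense Canopies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates leaf area index (LAI) from soil-adjusted vegetation
    indices and calibrates the SAVI soil adjustment factor X by exhaustive
    grid search over a linear LAI-VI regression, allowing negative X as is
    optimal under dense canopies where vegetation isolines intersect the
    soil line in the first quadrant of the red-NIR plane.  Includes the
    standard index formulas (NDVI, SAVI, TSAVI, EVI, GRVI), pixel and
    field-record screening with temporal matching of LAI composites to
    reflectance scenes, quarterly aggregation with classical multiplicative
    seasonal decomposition and an augmented Dickey-Fuller stationarity test
    using MacKinnon response surfaces, and a Beer-Lambert canopy simulator
    that reproduces soil-line and isoline geometry so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
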
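Package: forestpattern
Title: Landscape Pattern Trends from Annual Forest Change Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for deriving
    annual forest/non-forest maps from dense spectral time series and
    characterizing the temporal behaviour of landscape pattern. Includes a
    disturbance-and-recovery scene simulator, best-available-pixel
    compositing with gap interpolation and validity screening, Tasseled-Cap
    disturbance-index trajectory classification with spectral (NBR) recovery,
    minimum-mapping-unit filtering, landscape gridding at multiple extents,
    four class-level pattern indices (forest cover, largest patch index,
    edge density, core forest cover), Mann-Kendall/Theil-Sen trend inference
    with block-bootstrap confidence intervals, Moran's I spatial correlograms,
    temporal autocorrelation screening, and change-magnitude classification
    of landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
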
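Package: paleodown
Title: Debiasing, Downscaling and Bioclimatic Derivation of Paleo-to-Future
    Climate Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Change-factor debiasing and bilinear statistical downscaling of
    coarse climate-model output against fine-grid observational
    climatologies, covering additive, ratio (factor) and normalized-shortwave
    (gamma) variables; quantile-mapping bias correction for precipitation,
    including a linear variant for decadal paleo archives; constrained
    seasonal-to-monthly harmonization by smoothness minimization under exact
    seasonal-mean constraints (Lagrange multipliers); derived bioclimatic
    variables (growing degree days via a truncated-normal expectation,
    Penman-Monteith reference evapotranspiration, single-bucket actual
    evapotranspiration, top-of-atmosphere insolation); inverse-distance
    extrapolation of climate onto formerly exposed coastal shelf cells; and
    centennial/decadal statistical summaries with packed-integer NetCDF and
    GeoTIFF output conventions. Includes a synthetic-fixture generator so the
    full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    geosphere,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
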
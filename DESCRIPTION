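Package: forestscale
Title: Scale-Aware Forest Biomass Estimation from Canopy Height Rasters
Version: 0.1.0
Authors@R:
    person("Forest", "Biometrics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design-based, model-based and small-area estimators of forest
    aboveground biomass density from area-based canopy height metrics, with
    a multi-resolution prediction-scale experiment that quantifies how the
    support size of canopy metrics (10/25/44/100 m) biases model-based
    estimates relative to a plot-native baseline. Includes a synthetic
    landscape generator (autocorrelated canopy height fields, canopy gaps,
    power-law biomass link, systematic inventory-plot sampling) so the full
    pipeline is testable without proprietary inventory or lidar data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
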
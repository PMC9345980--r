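Package: rifagam
Title: Spatial Invasion-Risk Modelling for Red Imported Fire Ants with
    Penalized-Spline Logistic Additive Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based quantification of red imported fire ant (Solenopsis
    invicta) invasion outcomes from two-wave sampling-tube surveillance
    ("successful invasion or remaining at the highest level", SIRH),
    construction of land-use-change and road-distance covariates from planar
    land-use and road layers, and linear and nonlinear binomial risk models:
    a logistic GLM and two penalized-spline logistic additive models with
    factor-by distance smooths and a tensor-product spatial smooth, fitted by
    penalized IRLS with GCV smoothing selection.  Includes a seeded synthetic
    landscape and surveillance generator so the whole pipeline is testable
    without restricted surveillance data, model comparison by AIC and
    analysis of deviance, distance-threshold summaries and component-wise
    risk surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
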
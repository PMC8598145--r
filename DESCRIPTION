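Package: insertfactor
Title: Electron Insert (Cutout) Factor Prediction by Equivalent-Ellipse
    Spline Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting electron insert (cutout) output factors on
    clinical linear accelerators. Arbitrary cutout shapes are parameterized
    into equivalent ellipses (width from the largest inscribed circle, length
    from area equivalence), a bivariate least-squares spline is fitted to a
    small set of measured insert factors over the (width, perimeter-to-area
    ratio) plane, and factors for new shapes are interpolated from the model.
    Includes a measurement-database format, recommended bounding-shape
    measurement designs per applicator, DICOM RT Plan insert extraction,
    monitor-unit calculation, quadratic source-to-surface-distance
    interpolation, prediction reports, validation statistics for
    measured-versus-predicted comparisons, and a synthetic output-factor
    simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
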
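Package: lwpndvi
Title: Calibrating Leaf Water Potential Against Proximal-Sensing NDVI with
    Errors-in-Variables Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating leaf water potential (LWP, MPa) from
    canopy NDVI measured by a proximal active-optical sensor. Covers the
    full calibration pipeline: ingestion and filtering of raw reflectance
    scan logs (idle-record removal by GPS displacement, warm-up exclusion
    windows, UTC to local-time conversion), aggregation of NDVI and
    pressure-chamber LWP replicates to group means with standard errors,
    ordinary least-squares calibration with Taylor-propagated coefficient
    and prediction uncertainties, York/Williamson weighted least squares
    with independent measurement errors in both coordinates (iterative
    solution of the least-squares cubic, adjusted points, finite-difference
    coefficient variances), a with-replacement resampling study of how the
    LWP replicate count inflates coefficient uncertainty, and reporting of
    percent coefficient errors and uncertainty-to-range diagnostics. A
    synthetic field-campaign generator with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
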
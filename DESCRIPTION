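Package: corneatrace
Title: Corneal Raytracing, Best-Focus Power and Spherical Aberration
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Meridional (2D) raytracing through a two-surface conic model of
    the human cornea. Builds area-weighted collimated ray fans, refracts them
    through aspheric front and back corneal surfaces with Snell's law, and
    locates the best focal plane under four merit functions (RMS wavefront
    error, RMS ray scatter, mean absolute ray scatter, total spot diameter).
    Converts focal distance to corneal power referenced to the front apex,
    extracts the Zernike spherical-aberration coefficient Z40 over a 6 mm
    zone, fits customised keratometer indices and multivariate linear
    corneal-power models, and simulates synthetic biometry populations from
    truncated-Gaussian marginals for testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
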
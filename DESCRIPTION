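Package: gkvol
Title: Volume-Averaging Correction Factors for Gamma Knife Small-Field Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the elliptical 3D absorbed-dose distribution of
    Gamma Knife Perfexion collimated fields and for computing volume-averaging
    correction factors (k_vol) for dosimetry detectors. Principal-axis relative
    dose profiles are fitted with sums of error functions and composed into an
    analytical 3D dose model via squared-direction-cosine weighting. Detector
    active volumes (thimble ionization chambers with electrode and hemispherical
    cap, disks, boxes) are described parametrically, and k_vol is obtained by
    composite Simpson quadrature of the normalized dose over the active volume,
    together with clinical-to-reference field ratios and the volume-averaging
    contribution to the TRS-483 field output correction factor. Includes a
    synthetic profile and reference-point generator for end-to-end testing, a
    model-accuracy check against exported dose-point sets, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
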
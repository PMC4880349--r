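Package: polstripe
Title: Rotating-Polarizer Imaging Polarimetry of Striped Animal Coats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rotating-polarizer photographic polarimetry
    of striped animal coats. Reads co-registered image series taken through a
    linear polarizing filter at known angles, segments black and white stripes
    by maximizing between-class luminance variance, fits a 180-degree-period
    sinusoid of luminance against filter angle to estimate the degree and
    angle of linear polarization per stripe class, computes Michelson stripe
    contrast, simulates the low-acuity view of an approaching insect by
    distance-scaled Gaussian blur, and compares coat polarization against
    adjacent background vegetation. Includes a synthetic striped-scene
    generator with known ground truth so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
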
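Package: uvresolve
Title: Resolution and Chemometric Calibration of Overlapped UV-Vis Mixture Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying severely overlapped three-component UV-Vis
    mixtures. Implements successive ratio subtraction and successive derivative
    subtraction, each coupled with constant multiplication, on a uniform-grid
    spectrum type with gap-derivative, ratio-spectrum and plateau-constant
    primitives; a five-level three-factor orthogonal calibration design with
    PLS1 (NIPALS) regression, cross-validation, Haaland-Thomas latent-variable
    selection, forward interval-PLS and genetic-algorithm wavelength selection;
    ICH-style validation statistics (LOD/LOQ, recovery, precision), USP-style
    content-uniformity acceptance values, method-comparison tests, and a
    Gaussian-band synthetic spectrum generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
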
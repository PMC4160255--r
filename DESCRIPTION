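Package: ewdclim
Title: Earlywood-Density Dendroclimatology: Chronologies, Transfer
    Functions and Temperature Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building tree-ring density (or width) site
    chronologies and turning them into climate reconstructions. Covers
    negative-exponential detrending with a conservative fallback cascade,
    Tukey biweight robust chronology averaging, running Rbar and expressed
    population signal (EPS) with reliability truncation, bootstrapped
    correlation and principal-component response functions against monthly
    climate windows, linear transfer-function calibration with the classic
    dendroclimatic verification battery (leave-one-out cross-validation,
    reduction of error, sign test, product-means test), event
    classification and decadal warm/cold period segmentation of the
    reconstruction, generic gridded-field diagnostics (detrended spatial
    correlation, extreme-decile composites), and a fully seeded synthetic
    multi-core data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
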
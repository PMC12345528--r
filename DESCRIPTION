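Package: fnirscal
Title: Fecal NIRS Chemometric Calibration for Digestibility Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric calibration pipeline for fecal near-infrared
    reflectance spectroscopy (fNIRS) in poultry digestibility studies.
    Implements WinISI-style preprocessing (standard normal variate,
    detrend, multiplicative scatter correction, gap-segment derivative
    math treatments), modified partial least-squares (MPLS) regression
    with cross-validated factor selection, two-pass chemical (t) and
    spectral (global H) outlier elimination, full calibration and
    validation figures of merit (SEC, SECV, SEP, RPD, RER) with model
    quality classification, and indigestible-marker dry-matter
    digestibility estimation. A synthetic excreta-spectra generator with
    Beer-Lambert component mixing, affine scatter artifacts and marker
    mass balance supports testing and worked analyses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
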
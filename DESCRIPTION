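Package: dsfaspri
Title: Dual-Band Spectral Filter Array Surface Plasmon Resonance Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and analysis for snapshot surface plasmon
    resonance imaging (SPRi) read out through a checkerboard dual-band
    spectral filter array. Provides a wavelength-domain optical model
    (band-pass filters with raised-cosine edges, a Gaussian resonance dip
    with linear refractive-index response, band-intensity integration and
    the gamma spectral-contrast statistic), transfer-matrix simulation of
    multilayer dielectric filter stacks, a synthetic dual-band image
    simulator with refractive-index protocols, grid-boundary artifacts and
    detector noise, pixel-shift demosaicing, gamma-map and region-of-
    interest time-series extraction, and sensitivity / limit-of-detection
    calibration including a Gaussian-fit theoretical sensitivity procedure
    and concentration-LOD extrapolation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
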
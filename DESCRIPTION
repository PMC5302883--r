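Package: pigmentnoise
Title: Thermal Activation of Visual Pigments from Dark Noise and
    Microspectrophotometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying spontaneous (thermal) activation of
    visual pigments in photoreceptors. Implements the multi-vibrational-mode
    barrier-crossing prediction of the molecular thermal-activation rate
    from a pigment's peak absorption wavelength, two independent estimators
    of the quantal event rate from dark-current recordings (direct counting
    with amplitude and kinetics criteria, and the power-spectral-density
    difference method), and microspectrophotometric analysis of absorbance
    spectra including baseline correction, peak-wavelength estimation,
    polynomial template unmixing of chromophore isomers, and
    chromophore-exchange kinetics. A synthetic-data generator reproduces
    the statistical structure of suction-pipette recordings and
    single-cell absorbance spectra so that every analysis stage is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
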
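Package: nacreoptics
Title: Multilayer Interference Optics of Nacreous Layers and Structural Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the structural coloration of nacre-like multilayer
    stacks of aragonite platelets separated by thin interlamellar gaps, as
    found in fossilized ammonite shells (Ammolite) and modern mollusk
    shells.  Provides a stochastic generator of nacre-like layer stacks
    (truncated-Gaussian plate and gap thicknesses, constant or drifting
    lamination-period depth profiles), an exact one-dimensional
    transfer-matrix solver for reflectance spectra of planar stacks at any
    incidence angle and polarization, closed-form analytic models
    (Bragg-Snell peak prediction with an effective-medium index, Airy
    multiple-reflection reflectance of a single nanogap, bandwidth
    heuristics), spectral summaries (peak wavelength, full width at half
    maximum, off-band baseline), CIE 1931 colorimetry with a scalar
    saturation measure, and experiment runners that link structure to
    spectra to color.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
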
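Package: oasim
Title: Optoacoustic Pressure Transients in Layered Absorbing Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and approximate inversion of optoacoustic
    (photoacoustic) pressure transients generated in optically layered,
    acoustically homogeneous media under stress confinement. Implements an
    efficient cylindrical-coordinate evaluation of the optoacoustic Poisson
    integral with precomputed azimuthal weights and propagation-time binning,
    a brute-force Cartesian voxel solver for cross-validation, a
    finite-thickness transducer foil model, the near-field/far-field
    diffraction-parameter classifier, and far-field reconstruction of the
    initial acoustic stress depth profile by temporal integration, with
    mean-squared-error benchmarking against the exact Beer-Lambert profile.
    Bundled presets reproduce two-layer test scenarios and melanin-doped
    hydrogel tissue-phantom configurations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
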
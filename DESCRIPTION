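Package: motilitykit
Title: Bacterial Run-and-Tumble Trajectory Analytics and Differential
    Dynamic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for bacterial swimming behaviour in quasi-2D and
    3D. Provides a seeded simulator for circular run-and-tumble swimmers and
    Brownian controls together with a virtual microscope that renders
    phase-contrast-like and dark-field-like movies; per-trajectory behavioural
    statistics (frame-level kinematic features, two-state hidden-Markov tumble
    classification, covariance-based diffusion estimation, directional
    persistence); the closed-form circular run-and-tumble model (velocity
    autocorrelation and mean square displacement, population averaging over
    exponentially distributed curvatures) with least-squares fitting to
    empirical curves; differential dynamic microscopy (image structure
    function, Schulz-speed-distribution intermediate scattering function fits,
    path-straightness ratio) and dark-field flicker spectroscopy (cell-body
    angular velocity, processivity); and small phenotype utilities (molecular
    ruler calibration of hook length, motility-halo normalization, reporter
    relative light units).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
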
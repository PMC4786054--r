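Package: ptccd
Title: Simulation and Measurement-Error Models for Phosphor-Taper-CCD X-Ray Area Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A stochastic forward model of a phosphor-taper-CCD (p-t-CCD) X-ray
    area detector (phosphor absorption and scintillation gain, fibre-optic taper
    demagnification and radial distortion, CCD charge accumulation and read-out),
    together with the cascaded-gain noise algebra that describes it: cascade and
    pixel noise factors, gains, signal variance and zero-frequency detective
    quantum efficiency. Includes the image correction chain (dark subtraction,
    area-scaled flat fielding, distortion correction by polygon-overlap
    reapportioning), MOSFLM-style Bragg-spot summation and profile-fitting
    integration with Poisson, cascade-model and covariance-aware error
    estimates, replicate spot-ensemble drivers, and a calibration workflow that
    recovers the cascade parameters of a detector from tabular intensity
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
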
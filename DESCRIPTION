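Package: retpwv
Title: Retinal Venous Pulse Wave Velocity from Photoplethysmographic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures retinal venous pulse wave velocities within the optic
    disc from photoplethysmographic video. Per-pixel blood-column intensity
    time series along a vein centerline are fitted with a second-order
    harmonic regression (cardiac first and second harmonics, continuous
    piecewise-linear lighting trend, AR(1) errors, feasible generalized
    least squares). The spatial gradient of the first-harmonic phase yields
    signed pulse wave velocities on either side of a phase turning point,
    interpreted as the meeting point of two opposing pulse waves. Includes
    frame-stack preprocessing (sharpest-frame selection, affine
    co-registration, centerline extraction, distance calibration), a
    Gaussian fit to the pulse-amplitude hump, turning-point geometry
    metrics, per-subject summaries, pressure-matched video selection, the
    Pitman-Morgan paired-variance test, and a fully parameterised synthetic
    two-wave generator so that every stage is verifiable against known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    pracma,
    tiff,
    png,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
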
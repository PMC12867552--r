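Package: rnb
Title: Wavelet-Domain Separation of Rhythmic and Scale-Free Activity in
    Electrophysiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes the arrhythmic 1/f^beta (scale-free) background from
    electrophysiological recordings at the level of wavelet coefficients and
    synthesizes a purely rhythmic time series. Implements an orthonormal
    fractional spline wavelet transform on dyadic scales, a wavelet-domain
    estimator of the aperiodic scaling exponent, universal soft-threshold
    denoising, and 1/f rescaling of the coefficients ("Rhythms and
    Background"). Includes epoch-ensemble spectroscopy (scaling-exponent
    distributions and rhythmic power spectra), synthetic-data generators
    (power-law backgrounds, Jansen-Rit neural-mass and sinusoidal burst
    oscillations) with amplitude- and exponent-recovery experiments, and an
    event layer for NREM sleep analyses: slow-wave detection with
    gamma-based polarity, transition-frequency switcher classification,
    theta-burst detection, phase-amplitude coupling, and induced versus
    phase-locked event scalograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
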
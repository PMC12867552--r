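# rnb — separating rhythms from the scale-free background

Electrophysiological recordings mix transient oscillations (sleep slow
waves, spindles, alpha bursts) with an arrhythmic background whose power
spectrum follows a power law `1/f^beta`. Spectral parameterization methods
can split the two in the frequency domain, but they return no time series:
instantaneous phase, amplitude and phase–amplitude coupling stay
contaminated by the background. `rnb` removes the background at the level
of wavelet coefficients and synthesizes a purely *rhythmic* time series
for time-resolved analyses.

For an epoch expanded on an orthonormal fractional spline wavelet basis
(coefficients `w_jk` at dyadic scale `j`, plus a slow residue), the
pipeline is:

1. estimate the scaling exponent `beta*` as the weighted least-squares
   slope of the per-scale log2 power `D_j = log2(mean_k w_jk^2)` over
   scales `j1..j2` (weights `n_j = 2^-j N`);
2. re-analyze at the exponent-adapted order `alpha = a0 + beta*/2`;
3. soft-threshold every coefficient with the universal threshold
   `lambda = sigma * sqrt(2 ln N)`, `sigma = median(|w_1k|)/0.6745`;
4. rescale scale `j` by `2^(-j beta*/2)`, flattening the background's
   scale trend;
5. synthesize from scales `1..J` at order `alpha0`, omitting the residue.

The result (`extract_rhythmic()`) carries two series: `s_R`, the whitened
rhythmic series used for event detection and spectroscopy, and `s_A`,
synthesized from the same shrunken coefficients without the rescale, whose
band amplitudes stay in input units. The package also ships the validation
machinery: `1/f^beta` generators, a Jansen–Rit neural-mass alpha
generator, amplitude/exponent recovery experiments, and an NREM sleep
event layer (slow-wave detection with gamma-based polarity,
switcher classification, theta bursts, PAC, induced vs. phase-locked
scalograms). Audience: sleep/EEG methodologists and anyone needing
background-free rhythm analysis of 1/f-dominated signals.

## Worked example

Thirty 8-s epochs at 256 Hz: a scale-free background (`beta = 2.2`) with a
4-s neural-mass alpha burst at calibrated amplitude level 0.5.

```r
library(rnb)
fs <- 256
set.seed(42)
eps <- lapply(1:30, function(i) {
  bg <- gen_scale_free(2.2, 2048, fs)
  x <- compose_epoch(bg, list(oscillation_spec("neural_mass", 10.5,
         amplitude_level = 0.5, band = c(9, 12))), fs)
  suppressWarnings(extract_rhythmic(x, fs))
})
eps[[1]]
#> Rhythmic epoch: 2048 samples @ 256 Hz
#>   beta* = 2.449, sigma = 0.02888, lambda = 0.1128, retained 23.5% of coefficients

sp <- rhythmic_spectra(eps, fs)          # whitened-series spectroscopy
find_spectral_peaks(sp, 2, 45, min_prominence = 10)
#>   frequency        power
#> 1        10 0.0004053641

spA <- rhythmic_spectra(eps, fs, series = "amplitude")
median(vapply(seq_along(eps), function(i)
  band_amplitude(rhythmic_spectra(eps[i], fs, series = "amplitude"),
                 c(9, 12)), numeric(1)))
#> [1] 0.4833217
```

Reading the output: `beta* = 2.45` is the epoch's arrhythmic exponent
(the drawn value plus the documented upward bias from a surviving
oscillation); `lambda` is the universal shrinkage threshold and 23.5% of
coefficients survive it. The whitened ensemble spectrum has a single
prominent peak at 10 Hz — the neural-mass alpha — and the per-epoch
amplitude readout (median 0.48) recovers the simulated level 0.5 up to
the soft-threshold loss.

Event-level tools operate on the rhythmic series of real recordings:

```r
ev <- detect_ssw_adaptive(x_sleep, fs = 200, region_band = c(0.5, 2.5))
cl <- classify_switchers(ev)
compute_pac(x_sleep, 200, phase_band = c(0.5, 4), amp_band = c(10, 16))
```

A thin command-line front end wraps the same functions
(`inst/cli/rnb.R`; subcommands `simulate`, `rnb`, `spectroscopy`,
`events`, `pac`, `recover`), writing TSV tables plus a JSON provenance
record per run.

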
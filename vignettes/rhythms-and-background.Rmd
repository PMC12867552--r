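---
title: "Separating rhythms from the scale-free background: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating rhythms from the scale-free background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnb)
```

## The problem and the model

Electrophysiological recordings (EEG, intracranial EEG) superpose two kinds
of activity. Transient oscillations — sleep slow waves, spindles, alpha
bursts — occupy characteristic frequency bands. Underneath them runs an
*arrhythmic* background whose power spectrum follows a power law,

$$\Gamma(f) \approx \frac{c}{f^{\beta}} + \frac{c}{f^{\beta}} R(f),$$

with a scaling exponent $\beta$ (typically 1–3 in sleep) and a narrowband
rhythmic factor $R(f)$. Spectral parameterization tools can split the two
components *in the frequency domain*, but they cannot hand back a time
series: instantaneous phase, amplitude and phase–amplitude coupling (PAC)
estimates remain contaminated by background fluctuations.

This package removes the background at the level of *wavelet
coefficients*. An epoch is expanded on dyadic timescales
($n_j = 2^{-j}N$ coefficients $w_{jk}$ at scale $j$, plus a low-frequency
residue $s_r$); because a $1/f^\beta$ process contributes a predictable
per-scale variance ($\mathrm{E}\,w_{jk}^2 \propto 2^{j\beta}$ with the
conventions below), its imprint can be estimated and cancelled coefficient
by coefficient, and a purely rhythmic series synthesized from what
remains.

## The wavelet basis

The transform uses orthonormal *symmetric fractional spline* wavelets,
realized as frequency-sampled filter banks on the DFT grid with periodic
boundary conditions. Two properties motivate the family:

* the regularity (order) $\alpha$ can be any non-negative real, so the
  analysis order can be adapted *continuously* to the measured exponent
  ($\alpha = a_0 + \beta^*/2$), which is what decorrelates the exponent
  from the oscillatory content;
* the filters are exact on the DFT grid, so the analysis–synthesis round
  trip reconstructs to machine precision (the test suite bounds the
  relative error at $10^{-6}$ over 200 random signals per order; observed
  errors are near $10^{-15}$).

Atoms are L2-normalized ($2^{-j/2}$ scaling). With this normalization and
per-scale log power $D_j = \log_2\left(n_j^{-1}\sum_k w_{jk}^2\right)$,
the weighted least-squares slope of $D_j$ on $j$ (weights $n_j$) equals
the Fourier exponent $\beta$ directly — no affine remapping. This
convention was fixed by a generator–estimator calibration: on synthetic
$1/f^\beta$ epochs ($N = 2048$), the median bias of $\hat\beta$ is below
0.05 for $\beta \in \{1, 1.5, 2, 2.5\}$ (asserted at 0.15 in the tests).

The characteristic mother frequency $f_0$ (the scale-to-frequency map
$f_j = 2^{-j} f_0 f_s$) has no closed form for this family; it is computed
numerically once per basis as the spectral peak of the scale-1 atom.

## The per-epoch pipeline

`extract_rhythmic()` runs, for an epoch of length $N$ (zero-mean
detrended, symmetrically zero-padded to a power of two when necessary):

1. **Analysis** at base order $a_0 = 4$ over scales $1..\max(J, j_2)$.
2. **Exponent fit**: $\beta^*$ = weighted LS slope of $D_j$ over scales
   $j_1 = 1$ to $j_2 = 9$. Scales whose power sits more than ~12 orders
   of magnitude below the strongest fitted scale are excluded — they are
   numerically empty (this matters only for degenerate inputs such as
   re-processed rhythmic series).
3. **Adaptive re-analysis** at order $a_0 + \beta^*/2$ (the fit must
   precede the adaptation; a first pass at $a_0$ is the only causal
   ordering). A configuration flag disables the second pass for ablation.
4. **Soft shrinkage** with the universal threshold
   $\lambda = \sigma\sqrt{2\ln N}$, $\sigma = \mathrm{median}|w_{1\cdot}|/0.6745$
   estimated from the finest scale *of the pass being shrunk* (the
   adapted pass when enabled), $N$ the padded length.
5. **Rescaling**: scale $j$ multiplied by $2^{-j\beta^*/2}$, flattening
   the background's scale trend (shrinkage precedes rescaling because the
   rescaled coefficient is defined as the rescale *of the shrunken*
   coefficient; both are per-coefficient maps, so the composition is
   order-checkable and checked).
6. **Synthesis** at order $\alpha_0 = 4$ from scales $1..J$ ($J = 8$),
   omitting the residue — drifts and ultraslow activity live there.
   $\alpha_0 = 4$ balances spectral resolution (narrowband spindles)
   against temporal sharpness (broad slow waves).

Note that $j_2 = 9 > J = 8$: the exponent fit uses one scale more than
the synthesis. The coarsest scales are the least reliable (few
coefficients, edge effects), so the synthesis stays clear of them while
the fit, which weights scales by $n_j$, can still use scale 9.

### Two output series and their units

The $2^{-j\beta^*/2}$ rescale whitens the background but also warps
amplitude units per scale: a 10 Hz rhythm and a 3 Hz rhythm of equal
input amplitude come out of the whitened series `s_R` with different
gains. `s_R` is therefore the *detection substrate* (events, relative
spectral peaks, PAC), not an amplitude meter. For amplitude readouts the
object returned also carries `s_A`, synthesized from the same shrunken
coefficients *without* the rescale: band amplitudes of `s_A` are in input
units, and the recovery experiments read oscillation amplitudes from it.
This split resolves the unit ambiguity that a proportional rescale rule
leaves open, and it is what makes the amplitude-level calibration below
exact by construction.

### Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `j1`, `j2` | 1, 9 | scale range of the $\beta^*$ fit (octaves) |
| `J` | 8 | deepest scale synthesized |
| `a0` | 4 | base analysis order (dimensionless regularity) |
| `alpha0` | 4 | synthesis order |
| `adaptive_alpha` | on | re-analyze at $a_0 + \beta^*/2$ |
| `shrinkage` | on | universal soft threshold |

For 8-s epochs at 256 Hz ($N = 2048$) scale 4 sits near 11 Hz and scale
6 near 2.8 Hz; for 20-s sleep epochs at 200 Hz (padded to 4096) the map
shifts accordingly — `scale_frequencies()` reports it per decomposition.

## Ensemble spectroscopy

`rhythmic_spectra()` produces the two-panel ensemble view: the
distribution of per-epoch $\beta^*$ (Gaussian KDE, Silverman bandwidth —
a smooth density without tuning), and the across-epoch mean of per-epoch
Hann periodograms of the rhythmic series. The periodogram is normalized
so the one-sided spectrum sums to the signal variance; the single Hann
taper suppresses leakage from residual edges. Peak finding
(`find_spectral_peaks()`) requires strict local maxima (plateaus are not
peaks) filtered by a topographic peak-to-saddle power ratio; maxima
within floating-point residue of zero are discarded.

## Synthetic data: what it emulates, what it does not

`gen_scale_free()` draws $1/f^\beta$ backgrounds by Fourier-filtering
white noise (random phases, power-law amplitudes), standardized to unit
variance. `gen_neural_mass()` integrates the Jansen–Rit two-interneuron +
pyramidal population model with its canonical parameter set
($A = 3.25$, $B = 22$, $a = 100$, $b = 50$, $C = 135$ with the standard
connectivity proportions, uniform input drive 120–320 pulses/s), by
fixed-step Euler at 4 substeps per output sample; the pyramidal potential
oscillates near 10 Hz with the lower-frequency onset transient
characteristic of the model. `sinusoid_burst()` provides Tukey-tapered
(taper fraction 0.5) narrowband bursts for designs where the neural-mass
model's fixed alpha frequency does not apply.

These generators emulate: power-law backgrounds with per-epoch exponent
variability (SD 0.1 around a target), transient 4-s oscillations on 8-s
epochs, and concurrent rhythms in separate bands. They do **not**
emulate: spectral knees or multiple scale-free regimes, nonstationary
exponents within an epoch, line noise, artifacts, or volume-conduction
mixtures. Passing tests therefore certify the algorithm under a single
power-law background — not robustness to every feature of real
recordings.

## The recovery experiments

`run_recovery_experiment()` reproduces the validation study. Amplitude
levels are defined *on the same scale as the readout*: a level-$L$
oscillation is scaled so that, alone in a zero epoch, its band-peak
periodogram power equals $L$. Perfect recovery then has slope exactly 1,
which is the only operationalization under which recovered-vs-simulated
slopes are meaningful without unit bookkeeping. The 15 levels are
linearly spaced over one decade (0.1–1.0) against unit-variance
backgrounds — this puts oscillation amplitudes on the order of the
background SD, matching the single-trial examples the method targets. In
the dual design the fixed 13 Hz alpha sits at mid-decade (0.55).

Per condition (background target × level): 300 epochs with
$\beta \sim N(\mathrm{target}, 0.1)$, oscillation superimposed on 200
randomly chosen epochs, 60 random epochs analyzed (oscillation-free ones
enter the regressions with level 0). Backgrounds and oscillations are
generated for the analyzed epochs; readouts are the 9–12 Hz (alpha) or
1.5–4.5 Hz (delta) band peak of the `s_A` spectrum and $\beta^*$. The
full single design processes $45 \times 60 = 2700$ epochs of 2048
samples in a few minutes on one core; the dual design 900.

Two known couplings, both systematic rather than random: (i) soft
shrinkage subtracts $\lambda$ from every surviving coefficient, so the
lowest amplitude levels are attenuated most, slightly flattening
per-condition slopes — most visibly in the shallowest background, whose
larger finest-scale $\sigma$ gives the largest $\lambda$; (ii) an
oscillation that survives shrinkage necessarily carries energy at its own
scale, which leaks into the weighted exponent fit and inflates
$\beta^*$ for shallow backgrounds. The test suite quantifies both on the
full designs; the pure-background estimator itself is nearly unbiased
(bias $< 0.05$, SD $\approx 0.04$ at $N = 2048$).

## Event layer

All band definitions use zero-phase forward–backward 4th-order
Butterworth filters (zero phase is mandatory for landmark timing), with
reflection padding so start-up transients cannot masquerade as slow
excursions. Slow-wave detection pairs consecutive zero-crossing
half-waves of 125–1000 ms; since intracranial polarity is
montage-dependent, the downstate is the half-wave with lower gamma
(30–80 Hz) envelope power. All criteria are amplitude-free: rescaling a
recording changes no detection.

The region-adaptive detector re-runs detection in a spectroscopy-derived
delta sub-band and keeps events whose hyperpolarization peaks coincide
across passes within 250 ms. Coincidence alone cannot reject a strictly
narrowband rhythm *outside* the region band — band-pass attenuation
preserves its zero-crossing geometry, and the criteria are deliberately
amplitude-free — so the conjunction additionally requires the
region-band wave amplitude to reach half the matched canonical-band
amplitude. The ratio is scale-invariant, so the amplitude-free property
is preserved.

Switcher classification fits a two-component Gaussian mixture (EM, via
*mclust*, deterministic model-based initialization) to the transition
frequencies $f_{tr} = 1/(2\tau)$; the boundary is the equal-posterior
crossing between the component means. Theta bursts are +1 SD excursions
of the z-scored theta envelope containing a +3 SD peak, kept at 0.4–1 s
duration; the baseline statistics should come from the recording's epoch
ensemble, not the event window. PAC is the mean-corrected modulation
$|\langle A e^{i\varphi}\rangle - \langle A\rangle\langle
e^{i\varphi}\rangle|$, which is exactly 0 for constant amplitude and
exactly 0.5 for $A = 1 + \cos\varphi$ — both closed forms are asserted.
Event scalograms use the Morse analytic wavelet ($\beta = 20$,
$\gamma = 3$); induced power averages coefficient magnitudes across
events, phase-locked power transforms the event average.

## Numerical choices and degenerate inputs

* Filters are evaluated on the DFT grid; the spline autocorrelation sum
  is truncated at ±60 terms with an Euler–Maclaurin tail, keeping its
  error near $10^{-12}$ even at order 0.
* Non-dyadic epochs are mean-removed, symmetrically zero-padded, and
  cropped after synthesis; the pad region should be excluded from event
  statistics.
* An all-zero epoch returns a zero rhythmic series with
  $\beta^* = 0$ and retained fraction 0; an all-zero scale yields a
  flagged $-\infty$ log-power sentinel rather than an error.
* $\beta^*$ outside $[0, 4]$ triggers a warning (implausible regime for
  sleep electrophysiology).
* Frequently used filter banks are memoized; adapted orders vary per
  epoch, so the cache is cleared wholesale when it grows past 50 bases.

## Known limitations

* **Sparsity vs. idempotence.** On a background-only epoch the universal
  threshold zeroes essentially all fine-scale coefficients, so the
  whitened series is *lacunar*: re-analyzing it shows a rising power
  profile at fine scales (no survivors) and flatness only across the
  scales that retain coefficients. Exponent re-estimation on rhythmic
  series is therefore meaningful only over the surviving-scale range —
  the test suite asserts flatness there, not globally.
* **Strong oscillations bias $\beta^*$ upward**, most visibly for delta:
  in the dual design the delta level explains a measurable share of
  exponent variance. This coupling is systematic and could be calibrated
  out, but no such correction is applied here.
* A single power law per epoch: knees, multiple regimes and time-varying
  exponents are out of scope by design.
* Periodic boundary conditions make the coarsest scales wrap around;
  the residue absorbs most of it, and `j2`/`J` defaults keep the fit and
  synthesis away from the worst-affected scales.
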
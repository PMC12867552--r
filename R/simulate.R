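# Synthetic-data generators (power-law backgrounds, Jansen-Rit neural-mass
# and tapered sinusoidal bursts) and the amplitude/exponent recovery
# experiments that validate the pipeline.

#' Scale-free (1/f^beta) background epoch
#'
#' Filters white noise in the Fourier domain so the expected power spectrum
#' follows `f^-beta` while phases stay random, then standardizes to zero
#' mean and unit variance.
#'
#' @param beta Target Fourier exponent, `beta >= 0`.
#' @param n Epoch length in samples (power of two).
#' @param fs Sampling rate (Hz); only sets the nominal frequency axis.
#' @param seed Optional seed; identical seeds give bit-identical epochs.
#' @return Numeric vector of length `n`, zero mean, unit variance.
#' @export
gen_scale_free <- function(beta, n, fs, seed = NULL) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (!is_pow2(n)) stop("n must be a power of two", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- c(0, seq_len(n / 2), seq.int(n / 2 - 1, 1)) * fs / n
  amp <- c(0, f[-1]^(-beta / 2))
  z <- stats::fft(stats::rnorm(n)) * amp
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  as.numeric((x - mean(x)) / stats::sd(x))
}

#' Parameters of the Jansen-Rit neural mass model
#'
#' The standard phenomenological model of a pyramidal population coupled to
#' excitatory and inhibitory interneuron populations, with its canonical
#' parameter set: average synaptic gains `A` (excitatory, mV) and `B`
#' (inhibitory, mV), rate constants `a`, `b` (1/s), connectivity `C` with
#' the usual proportions `C1 = C`, `C2 = 0.8 C`, `C3 = C4 = 0.25 C`,
#' sigmoid parameters `v0` (mV), `e0` (1/s), `r` (1/mV), and a uniform
#' pulse-density input on `[p_min, p_max]` (1/s). With these values the
#' pyramidal potential oscillates in the alpha range (~10 Hz).
#'
#' @param A,B,a,b,C,v0,e0,r,p_min,p_max Model constants (see description).
#' @return A `neural_mass_params` list.
#' @export
neural_mass_params <- function(A = 3.25, B = 22, a = 100, b = 50, C = 135,
                               v0 = 6, e0 = 2.5, r = 0.56,
                               p_min = 120, p_max = 320) {
  if (a <= 0 || b <= 0) stop("rate constants must be positive", call. = FALSE)
  structure(list(A = A, B = B, a = a, b = b, C = C, v0 = v0, e0 = e0, r = r,
                 p_min = p_min, p_max = p_max),
            class = "neural_mass_params")
}

#' Simulate neural-mass alpha oscillations
#'
#' Integrates the Jansen-Rit system with a fixed-step Euler scheme at step
#' `1/(fs * oversample)` and returns the mean-removed pyramidal-population
#' potential, decimated to `fs`. Multiple independent trials are integrated
#' jointly (vectorized states).
#'
#' @param duration_s Duration in seconds (`duration_s * fs >= fs`).
#' @param fs Output sampling rate (Hz).
#' @param params A [neural_mass_params()] set.
#' @param seed Optional seed for the stochastic input drive.
#' @param n_trials Number of independent realizations.
#' @param oversample Integration substeps per output sample (default 4).
#' @return A numeric vector (`n_trials = 1`) or a samples-by-trials matrix.
#' @export
gen_neural_mass <- function(duration_s, fs, params = neural_mass_params(),
                            seed = NULL, n_trials = 1L, oversample = 4L) {
  stopifnot(inherits(params, "neural_mass_params"))
  n_out <- round(duration_s * fs)
  if (n_out < fs) stop("need at least 1 s of samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / (fs * oversample)
  m <- as.integer(n_trials)
  sigm <- function(v) 2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
  C1 <- params$C; C2 <- 0.8 * params$C
  C3 <- 0.25 * params$C; C4 <- 0.25 * params$C
  y <- matrix(0, 6L, m)
  out <- matrix(0, n_out, m)
  keep <- 0L
  for (it in seq_len(n_out * oversample)) {
    p <- stats::runif(m, params$p_min, params$p_max)
    s1 <- sigm(y[2, ] - y[3, ])
    y_new <- y
    y_new[1, ] <- y[1, ] + dt * y[4, ]
    y_new[2, ] <- y[2, ] + dt * y[5, ]
    y_new[3, ] <- y[3, ] + dt * y[6, ]
    y_new[4, ] <- y[4, ] + dt * (params$A * params$a * s1 -
                                   2 * params$a * y[4, ] - params$a^2 * y[1, ])
    y_new[5, ] <- y[5, ] + dt * (params$A * params$a *
                                   (p + C2 * sigm(C1 * y[1, ])) -
                                   2 * params$a * y[5, ] - params$a^2 * y[2, ])
    y_new[6, ] <- y[6, ] + dt * (params$B * params$b * C4 * sigm(C3 * y[1, ]) -
                                   2 * params$b * y[6, ] - params$b^2 * y[3, ])
    y <- y_new
    if (any(!is.finite(y))) {
      stop(sprintf("neural-mass integration diverged at step size %.3g s",
                   dt), call. = FALSE)
    }
    if (it %% oversample == 0L) {
      keep <- keep + 1L
      out[keep, ] <- y[2, ] - y[3, ]
    }
  }
  out <- sweep(out, 2, colMeans(out))
  if (m == 1L) out[, 1] else out
}

#' Tapered sinusoidal burst
#'
#' A sinusoid of the given frequency windowed by a Tukey (tapered cosine,
#' taper fraction 0.5) envelope, placed at `onset_s` within a zero epoch.
#'
#' @param freq Oscillation frequency (Hz).
#' @param n Epoch length (samples).
#' @param fs Sampling rate (Hz).
#' @param amplitude Peak amplitude of the sinusoid.
#' @param onset_s,duration_s Burst placement (s); the burst must fit in the
#'   epoch.
#' @return Numeric vector of length `n`.
#' @export
sinusoid_burst <- function(freq, n, fs, amplitude = 1, onset_s = 2,
                           duration_s = 4) {
  ni <- round(duration_s * fs)
  i0 <- round(onset_s * fs) + 1L
  if (i0 < 1L || i0 + ni - 1L > n) stop("burst does not fit in the epoch",
                                        call. = FALSE)
  tt <- seq(0, 1, length.out = ni)
  a <- 0.5
  w <- rep(1, ni)
  lo <- tt < a / 2; hi <- tt > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * tt[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * tt[hi] / a - 2 / a + 1)))
  x <- numeric(n)
  x[i0:(i0 + ni - 1L)] <- amplitude * sin(2 * pi * freq * (0:(ni - 1)) / fs) * w
  x
}

#' Describe one simulated oscillation
#'
#' @param generator `"neural_mass"` or `"sinusoid_burst"`.
#' @param frequency Nominal frequency (Hz). For the neural-mass generator
#'   this is descriptive (the model's alpha rhythm is intrinsic, ~10.5 Hz).
#' @param amplitude_level Calibrated amplitude level (> 0): the band-peak
#'   power the oscillation alone reads out at (see [compose_epoch()]).
#' @param onset_s,duration_s Placement within the epoch (defaults 2 s and
#'   4 s).
#' @param band Readout band `c(f_lo, f_hi)` used for calibration; defaults
#'   to `frequency + c(-1.5, 1.5)`.
#' @return An `oscillation_spec` list.
#' @export
oscillation_spec <- function(generator = c("neural_mass", "sinusoid_burst"),
                             frequency, amplitude_level, onset_s = 2,
                             duration_s = 4, band = NULL) {
  generator <- match.arg(generator)
  if (amplitude_level <= 0) stop("amplitude_level must be > 0", call. = FALSE)
  if (is.null(band)) band <- frequency + c(-1.5, 1.5)
  structure(list(generator = generator, frequency = frequency,
                 amplitude_level = amplitude_level, onset_s = onset_s,
                 duration_s = duration_s, band = band),
            class = "oscillation_spec")
}

# Scale a unit oscillation waveform so that its oscillation-only band-peak
# periodogram readout equals the requested level. Levels and readouts share
# one scale by construction, so perfect recovery has slope exactly 1.
calibrate_oscillation <- function(waveform_epoch, fs, band, level) {
  p0 <- max(epoch_periodogram(waveform_epoch, fs)$power[
    {f <- seq(0, fs / 2, length.out = length(waveform_epoch) %/% 2 + 1)
     f >= band[1] & f <= band[2]}])
  if (p0 <= 0) stop("oscillation has no power in its calibration band",
                    call. = FALSE)
  sqrt(level / p0)
}

#' Superimpose calibrated oscillations on a background epoch
#'
#' Each oscillation is generated (or taken from `waveforms`), placed in the
#' epoch, scaled so that its oscillation-only band-peak periodogram readout
#' equals its `amplitude_level`, and added to the background.
#'
#' @param background Numeric epoch (the scale-free background, or zeros).
#' @param oscillations List of [oscillation_spec()]s.
#' @param fs Sampling rate (Hz).
#' @param waveforms Optional list of pre-generated unit waveforms (burst
#'   only, `duration_s * fs` samples each), e.g. neural-mass realizations;
#'   by default each spec's generator is called.
#' @param seed Optional seed for stochastic generators.
#' @return Numeric epoch of the same length as `background`.
#' @export
compose_epoch <- function(background, oscillations, fs, waveforms = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(background)
  if (length(oscillations) == 0L) return(background)
  bands <- lapply(oscillations, `[[`, "band")
  if (length(bands) > 1L) {
    for (i in seq_along(bands)[-1]) {
      for (k in seq_len(i - 1)) {
        if (bands[[i]][1] <= bands[[k]][2] && bands[[k]][1] <= bands[[i]][2]) {
          warning("two oscillations occupy overlapping bands; their ",
                  "calibrated readouts will interfere", call. = FALSE)
        }
      }
    }
  }
  x <- background
  for (i in seq_along(oscillations)) {
    os <- oscillations[[i]]
    stopifnot(inherits(os, "oscillation_spec"))
    ni <- round(os$duration_s * fs)
    i0 <- round(os$onset_s * fs) + 1L
    if (i0 + ni - 1L > n) stop("oscillation window does not fit in epoch",
                               call. = FALSE)
    wave <- if (!is.null(waveforms)) {
      waveforms[[i]]
    } else if (os$generator == "neural_mass") {
      gen_neural_mass(os$duration_s, fs)
    } else {
      sinusoid_burst(os$frequency, ni, fs, amplitude = 1, onset_s = 0,
                     duration_s = os$duration_s)
    }
    placed <- numeric(n)
    placed[i0:(i0 + ni - 1L)] <- wave[seq_len(ni)]
    k <- calibrate_oscillation(placed, fs, os$band, os$amplitude_level)
    x <- x + k * placed
  }
  x
}

#' Amplitude and exponent recovery experiment
#'
#' Reproduces the simulation validation of the pipeline. In the
#' `single_alpha` design, 4-s neural-mass alpha oscillations at 15
#' calibrated amplitude levels are superimposed on scale-free backgrounds
#' drawn around three target exponents; in the `dual_delta_alpha` design a
#' 3 Hz delta burst at 15 levels coexists with a fixed-amplitude 13 Hz
#' alpha burst. Per condition, `n_epochs` backgrounds are generated with
#' per-epoch exponents `N(target, beta_sd)`, the oscillation is added to
#' `n_osc` randomly chosen epochs, and `n_analyzed` random epochs (with or
#' without oscillation, entering the regressions with level 0 when absent)
#' are processed with [extract_rhythmic()]. Readouts are the band-peak
#' amplitude of the `s_A` spectrum and the per-epoch `beta_star`; ordinary
#' least-squares regressions of the readouts on level (and background)
#' summarize recovery.
#'
#' @param design `"single_alpha"` or `"dual_delta_alpha"`.
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @param n_epochs,n_osc,n_analyzed Epoch counts per condition (defaults
#'   300/200/60).
#' @param levels Calibrated amplitude levels (default 15 values linearly
#'   spaced over the decade 0.1..1).
#' @param beta_targets Background exponent targets (defaults: 1.69, 2.11,
#'   2.49 for `single_alpha`; 2.11 for `dual_delta_alpha`).
#' @param beta_sd Per-epoch SD of the exponent draw (default 0.1).
#' @param fs,epoch_s Sampling rate and epoch duration (defaults 256 Hz,
#'   8 s).
#' @param alpha_fixed_level Fixed 13 Hz alpha level of the dual design
#'   (default 0.55, mid-decade).
#' @param config [rnb_config()] used for extraction.
#' @return A `recovery_experiment` with `epochs` (per-epoch table),
#'   `models` (fitted `lm` objects) and `summary` (slopes, R^2, t, p).
#' @export
run_recovery_experiment <- function(design = c("single_alpha", "dual_delta_alpha"),
                                    seed = 1L,
                                    n_epochs = 300L, n_osc = 200L,
                                    n_analyzed = 60L,
                                    levels = seq(0.1, 1, length.out = 15),
                                    beta_targets = NULL, beta_sd = 0.1,
                                    fs = 256, epoch_s = 8,
                                    alpha_fixed_level = 0.55,
                                    config = rnb_config()) {
  design <- match.arg(design)
  if (is.null(beta_targets)) {
    beta_targets <- if (design == "single_alpha") c(1.69, 2.11, 2.49) else 2.11
  }
  stopifnot(n_analyzed <= n_epochs, n_osc <= n_epochs)
  set.seed(as.integer(seed))
  N <- round(epoch_s * fs)
  rows <- list()
  for (bt in beta_targets) {
    for (L in levels) {
      betas <- stats::rnorm(n_epochs, bt, beta_sd)
      osc_idx <- sort(sample.int(n_epochs, n_osc))
      analyzed <- sort(sample.int(n_epochs, n_analyzed))
      osc_analyzed <- intersect(analyzed, osc_idx)
      n_waves <- length(osc_analyzed)
      if (design == "single_alpha") {
        waves <- gen_neural_mass(4, fs, n_trials = max(n_waves, 1L))
        if (n_waves == 1L) waves <- matrix(waves, ncol = 1)
      } else {
        waves <- matrix(sinusoid_burst(3, round(4 * fs), fs, 1, 0, 4),
                        ncol = 1)[, rep(1, max(n_waves, 1L)), drop = FALSE]
        alpha_wave <- sinusoid_burst(13, N, fs, 1, 2, 4)
        k_alpha <- calibrate_oscillation(alpha_wave, fs, c(11.5, 14.5),
                                         alpha_fixed_level)
      }
      wv <- 0L
      for (i in analyzed) {
        x <- gen_scale_free(max(betas[i], 0), N, fs)
        has_osc <- i %in% osc_idx
        if (has_osc) {
          wv <- wv + 1L
          placed <- numeric(N)
          placed[(round(2 * fs) + 1L):(round(2 * fs) + nrow(waves))] <-
            waves[, wv]
          band <- if (design == "single_alpha") c(9, 12) else c(1.5, 4.5)
          k <- calibrate_oscillation(placed, fs, band, L)
          x <- x + k * placed
        }
        if (design == "dual_delta_alpha") x <- x + k_alpha * alpha_wave
        ep <- suppressWarnings(extract_rhythmic(x, fs, config))
        sp <- rhythmic_spectra(list(ep), fs, series = "amplitude")
        row <- data.frame(
          beta_target = bt,
          level = if (has_osc) L else 0,
          condition_level = L,
          has_osc = has_osc,
          beta_star = ep$beta_star)
        if (design == "single_alpha") {
          row$amp <- band_amplitude(sp, c(9, 12))
        } else {
          row$delta_amp <- band_amplitude(sp, c(1.5, 4.5))
          row$alpha_amp <- band_amplitude(sp, c(11.5, 14.5))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  models <- list()
  if (design == "single_alpha") {
    tab$bg_c <- tab$beta_target - mean(beta_targets)
    models$amplitude <- stats::lm(amp ~ level * bg_c, data = tab)
    models$amplitude_by_bg <- lapply(split(tab, tab$beta_target),
                                     function(d) stats::lm(amp ~ level, data = d))
    models$beta_on_level <- stats::lm(beta_star ~ level, data = tab)
    models$beta_on_background <- if (length(beta_targets) > 1L) {
      stats::lm(beta_star ~ factor(beta_target), data = tab)
    } else {
      stats::lm(beta_star ~ 1, data = tab)
    }
  } else {
    models$delta_on_level <- stats::lm(delta_amp ~ level, data = tab)
    models$alpha_on_level <- stats::lm(alpha_amp ~ level, data = tab)
    models$beta_on_level <- stats::lm(beta_star ~ level, data = tab)
  }
  structure(list(design = design, seed = seed, epochs = tab, models = models,
                 summary = recovery_summary(design, models)),
            class = "recovery_experiment")
}

recovery_summary <- function(design, models) {
  pick <- function(fit, term, label) {
    cf <- summary(fit)$coefficients
    data.frame(model = label, term = term,
               estimate = cf[term, "Estimate"],
               t = cf[term, "t value"], p = cf[term, "Pr(>|t|)"],
               r_squared = summary(fit)$r.squared)
  }
  if (design == "single_alpha") {
    out <- rbind(
      pick(models$amplitude, "level", "amplitude"),
      pick(models$beta_on_level, "level", "beta_on_level"))
    slopes <- vapply(models$amplitude_by_bg,
                     function(f) stats::coef(f)[["level"]], numeric(1))
    out <- rbind(out, data.frame(
      model = "amplitude_by_bg", term = "min_slope",
      estimate = min(slopes), t = NA, p = NA,
      r_squared = summary(models$beta_on_background)$r.squared))
    out
  } else {
    rbind(pick(models$delta_on_level, "level", "delta_amplitude"),
          pick(models$alpha_on_level, "level", "alpha_amplitude"),
          pick(models$beta_on_level, "level", "beta_on_level"))
  }
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Recovery experiment (%s), seed %s: %d analyzed epochs\n",
              x$design, format(x$seed), nrow(x$epochs)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
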
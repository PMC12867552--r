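# Event layer: slow-wave detection with gamma-based polarity, switcher
# classification of transition frequencies, theta-burst detection,
# phase-amplitude coupling and induced/phase-locked event scalograms.
# All filters are zero-phase forward-backward Butterworth (4th order per
# pass), so event landmarks carry no filter delay.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), i.e. zero phase and 8th-order magnitude.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param band `c(f_lo, f_hi)` in Hz, inside (0, fs/2).
#' @return Filtered vector.
#' @export
bandpass_zerophase <- function(x, fs, band) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop("band must satisfy 0 < f_lo < f_hi < fs/2", call. = FALSE)
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  # reflection padding keeps filter start-up transients out of the signal,
  # so edge samples carry no spurious low-frequency excursions
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 * fs / band[1]))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(npad + 1):(npad + n)]
}

#' Analytic signal via the frequency domain
#'
#' @param x Numeric vector.
#' @return Complex vector `x + i * H(x)`; `Mod()` is the envelope, `Arg()`
#'   the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-crossing times of a filtered trace, linearly interpolated (s).
zero_crossings <- function(x, fs) {
  s <- sign(x)
  idx <- which(s[-length(s)] * s[-1] < 0)
  (idx - 1 + x[idx] / (x[idx] - x[idx + 1])) / fs
}

#' Detect sleep slow waves
#'
#' Candidate half-waves are the intervals between successive zero
#' crossings (linear interpolation) of the delta-filtered trace whose
#' durations fall within physiological limits (125-1000 ms); consecutive
#' valid half-waves are paired into biphasic wave candidates. Because
#' intracranial polarity is montage-dependent, the hyperpolarized downstate
#' is identified as the half-wave with the lower mean gamma-band envelope
#' power. All criteria are amplitude-free: rescaling the signal leaves
#' detections unchanged.
#'
#' @param x Numeric signal (>= 4 s).
#' @param fs Sampling rate; must exceed twice the gamma band's upper edge.
#' @param delta_band Delta filter band (Hz), default `c(0.5, 4)`.
#' @param gamma_band Gamma band for polarity (Hz), default `c(30, 80)`.
#' @param half_wave_limits Admissible half-wave durations (s), default
#'   `c(0.125, 1)`.
#' @return A data.frame (class `ssw_events`) with one row per wave:
#'   zero-crossing landmarks (`neg_zc_s` entering, `pos_zc_s` leaving the
#'   downstate), extremum times `hyper_peak_s` and `depol_peak_s`, the
#'   transition delay `tau_s`, transition frequency `f_tr_hz = 1/(2 tau)`,
#'   `polarity` (`"down_first"`/`"down_second"`), `start_s`, `stop_s`, and
#'   a `class` column (`NA` until [classify_switchers()] is applied).
#' @export
detect_ssw <- function(x, fs, delta_band = c(0.5, 4), gamma_band = c(30, 80),
                       half_wave_limits = c(0.125, 1)) {
  if (length(x) < 4 * fs) stop("signal must be at least 4 s long", call. = FALSE)
  if (fs <= 2 * gamma_band[2]) {
    stop("sampling rate too low for the gamma band", call. = FALSE)
  }
  empty <- data.frame(
    neg_zc_s = numeric(0), pos_zc_s = numeric(0), hyper_peak_s = numeric(0),
    depol_peak_s = numeric(0), tau_s = numeric(0), f_tr_hz = numeric(0),
    polarity = character(0), start_s = numeric(0), stop_s = numeric(0),
    class = character(0), peak_amp = numeric(0))
  class(empty) <- c("ssw_events", "data.frame")
  if (stats::sd(x) == 0) return(empty)
  xf <- bandpass_zerophase(x, fs, delta_band)
  zc <- zero_crossings(xf, fs)
  if (length(zc) < 3L) return(empty)
  dur <- diff(zc)
  ok <- dur >= half_wave_limits[1] & dur <= half_wave_limits[2]
  genv2 <- Mod(analytic_signal(bandpass_zerophase(x, fs, gamma_band)))^2
  tt <- (seq_along(x) - 1) / fs
  hw_stats <- function(a, b) {
    sel <- which(tt >= a & tt < b)
    peak_i <- sel[which.max(abs(xf[sel]))]
    list(peak_t = tt[peak_i], gpow = mean(genv2[sel]),
         peak_amp = abs(xf[peak_i]))
  }
  rows <- list()
  i <- 1L
  while (i < length(dur)) {
    if (ok[i] && ok[i + 1L]) {
      h1 <- hw_stats(zc[i], zc[i + 1L])
      h2 <- hw_stats(zc[i + 1L], zc[i + 2L])
      down_first <- h1$gpow <= h2$gpow
      hyper <- if (down_first) h1$peak_t else h2$peak_t
      depol <- if (down_first) h2$peak_t else h1$peak_t
      tau <- abs(depol - hyper)
      rows[[length(rows) + 1L]] <- data.frame(
        neg_zc_s = if (down_first) zc[i] else zc[i + 1L],
        pos_zc_s = if (down_first) zc[i + 1L] else zc[i + 2L],
        hyper_peak_s = hyper, depol_peak_s = depol,
        tau_s = tau, f_tr_hz = 1 / (2 * tau),
        polarity = if (down_first) "down_first" else "down_second",
        start_s = zc[i], stop_s = zc[i + 2L], class = NA_character_,
        peak_amp = max(h1$peak_amp, h2$peak_amp))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("ssw_events", "data.frame")
  out
}

#' Region-adaptive slow-wave detection (conjunction of two passes)
#'
#' Runs [detect_ssw()] with the canonical delta band and again with a
#' region-specific band centred on the locally dominant rhythmic delta
#' peak; the final inventory is the conjunction: region-band events whose
#' hyperpolarization peaks coincide (within `tolerance_s`) with an event
#' from the canonical pass.
#'
#' Because the detection criteria are amplitude-free, a strictly
#' narrowband rhythm lying outside the region band would survive the
#' region-pass filter as an attenuated copy with unchanged zero-crossing
#' geometry; the conjunction therefore additionally requires the
#' region-band wave amplitude to be commensurate with (at least half of)
#' the matched canonical-band wave amplitude, which is the scale-invariant
#' reading of "maximal rhythmic content in the region band".
#'
#' @inheritParams detect_ssw
#' @param region_band Region-adaptive band (Hz), a sub-band of the delta
#'   range identified from the spectroscopy of the region.
#' @param tolerance_s Hyper-peak coincidence tolerance (default 0.25 s).
#' @param min_amp_ratio Minimum region-to-canonical wave amplitude ratio
#'   (default 0.5).
#' @return An `ssw_events` data.frame.
#' @export
detect_ssw_adaptive <- function(x, fs, region_band, delta_band = c(0.5, 4),
                                gamma_band = c(30, 80), tolerance_s = 0.25,
                                min_amp_ratio = 0.5) {
  if (region_band[1] < 0.1 || region_band[2] > fs / 2) {
    stop("region_band must lie within [0.1, fs/2]", call. = FALSE)
  }
  pass1 <- detect_ssw(x, fs, delta_band, gamma_band)
  pass2 <- detect_ssw(x, fs, region_band, gamma_band)
  if (nrow(pass2) == 0L || nrow(pass1) == 0L) return(pass2[0, ])
  keep <- vapply(seq_len(nrow(pass2)), function(i) {
    d <- abs(pass1$hyper_peak_s - pass2$hyper_peak_s[i])
    m <- which.min(d)
    d[m] <= tolerance_s &&
      pass2$peak_amp[i] >= min_amp_ratio * pass1$peak_amp[m]
  }, logical(1))
  out <- pass2[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify slow waves into slow and fast switchers
#'
#' Fits a two-component Gaussian mixture (EM, via \pkg{mclust}) to the
#' transition-frequency distribution; the lower-mean component is labelled
#' `"slow"`. The class boundary is the equal-posterior crossing between the
#' two component means.
#'
#' @param events An `ssw_events` data.frame (>= 10 events with finite
#'   transition frequency).
#' @param seed Seed for the (deterministic) fit, recorded for provenance.
#' @return A list with `labels` (factor `"slow"`/`"fast"` per event),
#'   `threshold_hz`, `single_class` flag, and the fitted `model`. With a
#'   degenerate (constant) distribution, a single-class result is returned
#'   with `threshold_hz = NA`.
#' @export
classify_switchers <- function(events, seed = 1L) {
  ftr <- events$f_tr_hz
  ftr_ok <- ftr[is.finite(ftr)]
  if (length(ftr_ok) < 10L) {
    stop("switcher classification needs at least 10 events with finite ",
         "transition frequency", call. = FALSE)
  }
  if (stats::sd(ftr_ok) == 0) {
    return(list(labels = factor(rep("slow", nrow(events)),
                                levels = c("slow", "fast")),
                threshold_hz = NA_real_, single_class = TRUE, model = NULL))
  }
  set.seed(as.integer(seed))
  fit <- Mclust(ftr_ok, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    fit <- Mclust(ftr_ok, G = 2, modelNames = "E", verbose = FALSE)
  }
  mu <- fit$parameters$mean
  slow_comp <- which.min(mu)
  pro <- fit$parameters$pro
  sdev <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdev) == 1L) sdev <- rep(sdev, 2)
  post_diff <- function(t) {
    pro[slow_comp] * stats::dnorm(t, mu[slow_comp], sdev[slow_comp]) -
      pro[-slow_comp] * stats::dnorm(t, mu[-slow_comp], sdev[-slow_comp])
  }
  lo <- min(mu); hi <- max(mu)
  threshold <- if (post_diff(lo) * post_diff(hi) < 0) {
    stats::uniroot(post_diff, c(lo, hi))$root
  } else {
    mean(mu)
  }
  labels <- factor(ifelse(is.finite(ftr) & ftr <= threshold, "slow", "fast"),
                   levels = c("slow", "fast"))
  list(labels = labels, threshold_hz = threshold, single_class = FALSE,
       model = fit)
}

#' Detect theta bursts
#'
#' The theta-band analytic envelope is z-scored against a baseline (by
#' default the signal's own envelope mean/SD; for multi-epoch recordings
#' pass the ensemble statistics). Events are contiguous regions where the
#' z-scored envelope exceeds +1 and reaches a peak of at least +3, with
#' start/stop at the +1 crossings; only durations within
#' `duration_limits` are kept.
#'
#' @param x Numeric signal (>= 4 s).
#' @param fs Sampling rate (Hz).
#' @param theta_band Theta band (Hz), default `c(4.6, 9.4)` (7 +/- 2.4 Hz).
#' @param baseline Optional `list(mean =, sd =)` of the theta envelope
#'   across the recording's epoch ensemble.
#' @param duration_limits Admissible burst durations (s), default
#'   `c(0.4, 1)`.
#' @return A data.frame (class `tb_events`) with `start_s`, `stop_s`,
#'   `peak_s`, `duration_s`, `peak_z`.
#' @export
detect_theta_bursts <- function(x, fs, theta_band = c(4.6, 9.4),
                                baseline = NULL,
                                duration_limits = c(0.4, 1)) {
  if (length(x) < 4 * fs) stop("signal must be at least 4 s long", call. = FALSE)
  env <- Mod(analytic_signal(bandpass_zerophase(x, fs, theta_band)))
  if (is.null(baseline)) baseline <- list(mean = mean(env), sd = stats::sd(env))
  empty <- data.frame(start_s = numeric(0), stop_s = numeric(0),
                      peak_s = numeric(0), duration_s = numeric(0),
                      peak_z = numeric(0))
  class(empty) <- c("tb_events", "data.frame")
  if (!is.finite(baseline$sd) || baseline$sd == 0) return(empty)
  z <- (env - baseline$mean) / baseline$sd
  above <- z >= 1
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    sel <- starts[k]:ends[k]
    pz <- max(z[sel])
    if (pz < 3) next
    dur <- length(sel) / fs
    if (dur < duration_limits[1] || dur > duration_limits[2]) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = (starts[k] - 1) / fs, stop_s = ends[k] / fs,
      peak_s = (sel[which.max(z[sel])] - 1) / fs,
      duration_s = dur, peak_z = pz)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("tb_events", "data.frame")
  out
}

#' Mean-corrected phase-amplitude modulation statistic
#'
#' `|mean(A e^{i phi}) - mean(A) mean(e^{i phi})|`: the magnitude of the
#' covariance between an amplitude series and the unit phasor of a phase
#' series. Subtracting the means removes spurious coupling from amplitude
#' offsets and non-uniform phase distributions; a constant amplitude gives
#' exactly 0, and `A = 1 + cos(phi)` over whole cycles gives exactly 0.5.
#'
#' @param A Amplitude series (non-negative).
#' @param phi Phase series (radians), same length.
#' @return A non-negative scalar, bounded by `mean(abs(A - mean(A)))`-type
#'   quantities (Cauchy-Schwarz).
#' @export
pac_modulation <- function(A, phi) {
  stopifnot(length(A) == length(phi))
  Mod(mean(A * exp(1i * phi)) - mean(A) * mean(exp(1i * phi)))
}

#' Phase-amplitude coupling of two bands over a window
#'
#' Band-passes the signal in the phase and amplitude bands (zero-phase),
#' takes analytic phase and amplitude, and evaluates [pac_modulation()]
#' over the half-open window `[t0, t1)`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param phase_band,amp_band Bands in Hz (e.g. delta `c(0.5, 4)` for
#'   phase, sigma `c(10, 16)` for amplitude).
#' @param window `c(t0, t1)` in seconds; must span at least two cycles of
#'   the phase band's low edge. Default: the whole signal.
#' @return A `pac_result` list: `value`, `phase_band`, `amp_band`,
#'   `window_s`, `n_samples`.
#' @export
compute_pac <- function(x, fs, phase_band, amp_band, window = NULL) {
  if (is.null(window)) window <- c(0, length(x) / fs)
  T_win <- diff(window)
  if (T_win < 2 / phase_band[1]) {
    stop("window must span at least two cycles of the phase band's low edge",
         call. = FALSE)
  }
  tt <- (seq_along(x) - 1) / fs
  sel <- which(tt >= window[1] & tt < window[2])
  phi <- Arg(analytic_signal(bandpass_zerophase(x, fs, phase_band)))[sel]
  A <- Mod(analytic_signal(bandpass_zerophase(x, fs, amp_band)))[sel]
  structure(list(value = pac_modulation(A, phi), phase_band = phase_band,
                 amp_band = amp_band, window_s = T_win,
                 n_samples = length(sel)),
            class = "pac_result")
}

# Morse analytic wavelet transform (frequency-domain), peak-normalized so
# the coefficient magnitude of a unit sinusoid equals 1 at its frequency.
morse_cwt <- function(x, fs, freqs, morse_beta = 20, morse_gamma = 3) {
  n <- length(x)
  X <- stats::fft(x)
  wk <- 2 * pi * (0:(n - 1)) / n
  wk[wk > pi] <- 0   # analytic: positive frequencies only
  xp <- (morse_beta / morse_gamma)^(1 / morse_gamma)
  W <- matrix(0 + 0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- xp / (2 * pi * freqs[i] / fs)
    sw <- s * wk
    psi <- numeric(n)
    pos <- sw > 0
    psi[pos] <- 2 * exp(morse_beta * log(sw[pos]) - sw[pos]^morse_gamma -
                          (morse_beta * log(xp) - xp^morse_gamma))
    W[i, ] <- stats::fft(X * psi, inverse = TRUE) / n
  }
  W
}

#' Induced and phase-locked event scalograms
#'
#' Time-frequency maps of event-aligned windows using the Morse analytic
#' wavelet (`beta = 20`, `gamma = 3`). Induced power averages coefficient
#' magnitudes across windows (total event-related power); phase-locked
#' power is the coefficient magnitude of the across-event average
#' (phase-consistent activity only). For a single window the two are
#' identical.
#'
#' @param windows Matrix of aligned windows (events in rows) or a list of
#'   equal-length numeric vectors.
#' @param fs Sampling rate (Hz).
#' @param mode `"induced"` or `"phase_locked"`.
#' @param freqs Frequency grid (Hz); default 32 log-spaced values from 2 Hz
#'   to `min(45, fs/2.5)`.
#' @param morse_beta,morse_gamma Morse wavelet parameters.
#' @return A list with `freq`, `time` (s, window-relative), and `power`
#'   (frequencies in rows).
#' @export
event_scalograms <- function(windows, fs, mode = c("induced", "phase_locked"),
                             freqs = NULL, morse_beta = 20, morse_gamma = 3) {
  mode <- match.arg(mode)
  if (is.list(windows) && !is.matrix(windows)) {
    lens <- lengths(windows)
    if (length(unique(lens)) != 1L) stop("ragged windows", call. = FALSE)
    windows <- do.call(rbind, windows)
  }
  if (nrow(windows) < 1L) stop("need at least one window", call. = FALSE)
  if (is.null(freqs)) {
    freqs <- exp(seq(log(2), log(min(45, fs / 2.5)), length.out = 32))
  }
  power <- if (mode == "induced") {
    acc <- 0
    for (i in seq_len(nrow(windows))) {
      acc <- acc + Mod(morse_cwt(windows[i, ], fs, freqs, morse_beta,
                                 morse_gamma))
    }
    acc / nrow(windows)
  } else {
    Mod(morse_cwt(colMeans(windows), fs, freqs, morse_beta, morse_gamma))
  }
  list(freq = freqs, time = (seq_len(ncol(windows)) - 1) / fs, power = power)
}

#' Contrast phase-amplitude coupling between two event groups
#'
#' Extracts a fixed-length window around each event's landmark, computes
#' per-event PAC, and compares the two samples with a Mann-Whitney
#' rank-sum test.
#'
#' @param events_a,events_b `ssw_events` data.frames (non-empty).
#' @param x Signal the events refer to.
#' @param fs Sampling rate (Hz).
#' @param phase_band,amp_band PAC bands (Hz).
#' @param window_s Window length centred on the landmark (default 4 s).
#' @param landmark Column holding the centre time: `"hyper_peak_s"` for
#'   standard analyses, `"pos_zc_s"` (the transition midpoint) for
#'   switcher contrasts.
#' @return A list with `pac_a`, `pac_b`, `statistic`, `p_value`,
#'   `median_diff`.
#' @export
pac_contrast <- function(events_a, events_b, x, fs, phase_band, amp_band,
                         window_s = 4, landmark = "hyper_peak_s") {
  if (nrow(events_a) == 0L || nrow(events_b) == 0L) {
    stop("both event groups must be non-empty", call. = FALSE)
  }
  per_event <- function(ev) {
    vals <- vapply(ev[[landmark]], function(ctr) {
      w <- c(ctr - window_s / 2, ctr + window_s / 2)
      if (w[1] < 0 || w[2] > length(x) / fs) return(NA_real_)
      compute_pac(x, fs, phase_band, amp_band, w)$value
    }, numeric(1))
    vals[is.finite(vals)]
  }
  pac_a <- per_event(events_a)
  pac_b <- per_event(events_b)
  wt <- stats::wilcox.test(pac_a, pac_b, exact = FALSE)
  list(pac_a = pac_a, pac_b = pac_b, statistic = unname(wt$statistic),
       p_value = wt$p.value,
       median_diff = stats::median(pac_a) - stats::median(pac_b))
}

#' Tag slow waves co-occurring with theta bursts
#'
#' Adds a logical `tb_cooccur` column: `TRUE` when a theta-burst peak lies
#' within `gap_s` of the wave's hyperpolarization peak.
#'
#' @param ssw An `ssw_events` data.frame.
#' @param tbs A `tb_events` data.frame.
#' @param gap_s Co-occurrence threshold in seconds (default 0.5).
#' @return `ssw` with the added `tb_cooccur` column.
#' @export
tag_tb_cooccurrence <- function(ssw, tbs, gap_s = 0.5) {
  ssw$tb_cooccur <- vapply(ssw$hyper_peak_s, function(t0) {
    nrow(tbs) > 0L && any(abs(tbs$peak_s - t0) < gap_s)
  }, logical(1))
  ssw
}
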
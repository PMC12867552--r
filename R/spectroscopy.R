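# Epoch-ensemble outputs: the distribution of scaling exponents across
# epochs and the averaged Fourier spectrum of the rhythmic series -- the
# two-panel "spectroscopy" view of a recording.

#' One-sided Hann periodogram
#'
#' Single-taper (Hann) periodogram with power-per-bin normalization: the
#' sum of the one-sided spectrum equals the signal variance (Parseval),
#' which is the convention the amplitude-level calibration of the
#' simulation experiments relies on.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @return A list with `freq` (Hz, from 0 to Nyquist) and `power`.
#' @export
epoch_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  X <- stats::fft((x - mean(x)) * w)
  U <- sum(w^2)
  p <- (Mod(X)^2 / (n * U))[1:(n %/% 2 + 1)]
  if (n %/% 2 >= 2) p[2:(n %/% 2)] <- 2 * p[2:(n %/% 2)]
  list(freq = (0:(n %/% 2)) * fs / n, power = p)
}

#' Ensemble spectroscopy of rhythmic epochs
#'
#' Per-epoch one-sided Hann periodograms of the rhythmic series, their
#' across-epoch average, the ensemble of per-epoch scaling exponents, and a
#' Gaussian kernel density (Silverman bandwidth) over the exponents.
#'
#' @param epochs List of [extract_rhythmic()] results with common length
#'   and sampling rate.
#' @param fs Sampling rate (Hz); defaults to the epochs' own.
#' @param series Which rhythmic series to use: `"whitened"` (`s_R`, the
#'   background-flattened series, default) or `"amplitude"` (`s_A`, in
#'   input units; used by the amplitude-recovery readouts).
#' @return A `spectroscopy_result` with `freq`, `psd_epochs` (epochs in
#'   rows), `psd_mean`, `beta_values`, `beta_density`.
#' @export
rhythmic_spectra <- function(epochs, fs = NULL,
                             series = c("whitened", "amplitude")) {
  series <- match.arg(series)
  if (length(epochs) < 1L) stop("need at least one epoch", call. = FALSE)
  if (inherits(epochs, "rhythmic_epoch")) epochs <- list(epochs)
  field <- if (series == "whitened") "s_R" else "s_A"
  lens <- vapply(epochs, function(e) length(e[[field]]), 1L)
  if (length(unique(lens)) != 1L) {
    stop("epochs have heterogeneous lengths", call. = FALSE)
  }
  if (is.null(fs)) fs <- epochs[[1]]$fs
  pg <- lapply(epochs, function(e) epoch_periodogram(e[[field]], fs))
  psd <- do.call(rbind, lapply(pg, `[[`, "power"))
  betas <- vapply(epochs, `[[`, numeric(1), "beta_star")
  dens <- if (length(betas) >= 2L && stats::sd(betas) > 0) {
    stats::density(betas, bw = "nrd0")
  } else NULL
  structure(
    list(freq = pg[[1]]$freq, psd_epochs = psd, psd_mean = colMeans(psd),
         beta_values = betas, beta_density = dens, fs = fs, series = series),
    class = "spectroscopy_result"
  )
}

#' @export
print.spectroscopy_result <- function(x, ...) {
  cat(sprintf(
    "Spectroscopy of %d epoch(s) [%s series]: %d frequency bins up to %g Hz\n  beta*: median %.3f (IQR %.3f-%.3f)\n",
    nrow(x$psd_epochs), x$series, length(x$freq), max(x$freq),
    stats::median(x$beta_values),
    stats::quantile(x$beta_values, 0.25), stats::quantile(x$beta_values, 0.75)))
  invisible(x)
}

#' Find spectral peaks in a band
#'
#' Strict local maxima of the averaged rhythmic spectrum within
#' `[fmin, fmax]`, filtered by topographic prominence and sorted by power
#' (descending). Plateaus are not peaks: a peak must strictly exceed both
#' neighbours. Prominence is measured as the ratio of the peak power to
#' its key saddle: on each side, the minimum power between the peak and
#' the nearest higher point (or the band edge) is found, and the larger of
#' the two minima is the saddle. This keeps window-leakage sidelobes out
#' while retaining genuinely separate rhythms.
#'
#' @param result A `spectroscopy_result`.
#' @param fmin,fmax Band edges (Hz), `fmin < fmax`, within Nyquist.
#' @param min_prominence Minimum peak-to-saddle power ratio (default 2).
#' @return A data.frame with columns `frequency` and `power` (possibly
#'   zero rows).
#' @export
find_spectral_peaks <- function(result, fmin, fmax, min_prominence = 2) {
  stopifnot(inherits(result, "spectroscopy_result"))
  if (!(fmin < fmax) || fmax > max(result$freq)) {
    stop("invalid band", call. = FALSE)
  }
  sel <- which(result$freq >= fmin & result$freq <= fmax)
  if (length(sel) == 0L) stop("empty band", call. = FALSE)
  p <- result$psd_mean
  lo <- min(sel); hi <- max(sel)
  is_peak <- vapply(sel, function(i) {
    i > 1L && i < length(p) && p[i] > p[i - 1L] && p[i] > p[i + 1L]
  }, logical(1))
  saddle <- function(i) {
    left <- i; m_left <- p[i]
    while (left > lo && p[left] <= p[i]) {
      left <- left - 1L
      m_left <- min(m_left, p[left])
    }
    right <- i; m_right <- p[i]
    while (right < hi && p[right] <= p[i]) {
      right <- right + 1L
      m_right <- min(m_right, p[right])
    }
    max(m_left, m_right)
  }
  # numerical floor: maxima more than ~12 orders of magnitude below the
  # strongest in-band power are floating-point residue, not rhythms
  keep <- sel[is_peak & p[sel] > max(p[sel]) * 1e-12]
  if (length(keep)) {
    prom <- vapply(keep, function(i) {
      s <- saddle(i)
      if (s <= 0) Inf else p[i] / s
    }, numeric(1))
    keep <- keep[prom >= min_prominence]
  }
  keep <- keep[order(p[keep], decreasing = TRUE)]
  data.frame(frequency = result$freq[keep], power = p[keep])
}

#' Band amplitude readout
#'
#' The "maximal rhythmic amplitude" readout of the recovery experiments:
#' either the peak of the averaged spectrum within a band (`mode = "peak"`,
#' default) or the trapezoidal band integral (`mode = "integral"`).
#'
#' @param result A `spectroscopy_result`.
#' @param band Numeric `c(f_lo, f_hi)` in Hz.
#' @param mode `"peak"` or `"integral"`.
#' @return A single non-negative number.
#' @export
band_amplitude <- function(result, band, mode = c("peak", "integral")) {
  stopifnot(inherits(result, "spectroscopy_result"))
  mode <- match.arg(mode)
  sel <- which(result$freq >= band[1] & result$freq <= band[2])
  if (length(sel) == 0L) stop("band outside the frequency grid", call. = FALSE)
  p <- result$psd_mean[sel]
  if (mode == "peak") {
    max(p)
  } else {
    f <- result$freq[sel]
    if (length(sel) < 2L) return(0)
    sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  }
}

#' Write spectroscopy tables
#'
#' Writes two TSV tables: the averaged spectrum (`freq`, `psd_mean`) and
#' the per-epoch exponents (`epoch_id`, `beta_star`).
#'
#' @param result A `spectroscopy_result`.
#' @param spectrum_path,beta_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_spectroscopy <- function(result, spectrum_path, beta_path) {
  stopifnot(inherits(result, "spectroscopy_result"))
  utils::write.table(
    data.frame(freq = result$freq, psd_mean = result$psd_mean),
    spectrum_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(epoch_id = seq_along(result$beta_values),
               beta_star = result$beta_values),
    beta_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(spectrum_path, beta_path))
}
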
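# Shared fixtures: everything is generated in code at test time.

FS <- 256
NEP <- 2048

# Epoch with a scale-free background and an optional calibrated oscillation.
fixture_epoch <- function(beta = 2.2, level = NULL, freq = 10.5, seed = 1) {
  bg <- gen_scale_free(beta, NEP, FS, seed = seed)
  if (is.null(level)) return(bg)
  osc <- numeric(NEP)
  osc[(2 * FS + 1):(6 * FS)] <- gen_neural_mass(4, FS, seed = seed + 1000)
  k <- rnb:::calibrate_oscillation(osc, FS, c(9, 12), level)
  bg + k * osc
}

quiet_extract <- function(x, fs = FS, config = rnb_config()) {
  suppressWarnings(extract_rhythmic(x, fs, config))
}

# Weighted-LS slope of log2 scale power, as an independent check path.
fit_beta_of <- function(x, alpha = 4, j1 = 1, j2 = 9) {
  basis <- build_basis(alpha, length(x), j2)
  dec <- wavedec(x, basis, J = j2)
  D <- scale_log_power(dec)
  estimate_beta(D, vapply(dec$coefficients, length, 1L), j1, j2)
}

# Log-log least-squares slope of an averaged periodogram (oracle for the
# scale-free generator), fitted between fmin and fmax.
loglog_slope <- function(psd_mean, freq, fmin = 0.5, fmax = 100) {
  sel <- freq >= fmin & freq <= fmax & psd_mean > 0
  unname(coef(lm(log(psd_mean[sel]) ~ log(freq[sel])))[2])
}
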
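# Orthonormal symmetric fractional spline wavelets, realized as
# frequency-sampled filter banks on the DFT grid (periodic boundary).
# Fractional orders alpha >= 0 are admissible, which is what makes the
# 1/f^beta rescaling of coefficients well defined at non-integer exponents.

# Autocorrelation A(nu) = sum_n |sinc(nu + n)|^(2 alpha + 2) of the symmetric
# fractional B-spline, with an Euler-Maclaurin tail so that the truncation
# error stays below ~1e-10 even at alpha = 0.
fs_autocorr <- function(alpha, nu) {
  p <- 2 * alpha + 2
  K <- 60L
  n <- seq.int(-K, K)
  S <- rowSums(outer(nu, n, function(v, m) {
    x <- v + m
    out <- abs(sin(pi * x) / (pi * x))^p
    out[x == 0] <- 1
    out
  }))
  tail_from <- function(a) a^(1 - p) / (p - 1) + a^(-p) / 2 + p * a^(-p - 1) / 12
  S + (abs(sin(pi * nu)) / pi)^p * (tail_from(K + 1 + nu) + tail_from(K + 1 - nu))
}

# Low/high-pass pair on an M-point DFT grid. The quadrature mirror relation
# G(w) = exp(-iw) H(w + pi) together with A(2 nu) = cos^.. A + sin^.. A(nu+1/2)
# gives |H|^2 + |G|^2 = 2 exactly on the grid, hence perfect reconstruction.
fs_filters <- function(alpha, M) {
  nu <- (0:(M - 1)) / M
  A1 <- fs_autocorr(alpha, nu)
  A2 <- fs_autocorr(alpha, (2 * nu) %% 1)
  H <- sqrt(2) * abs(cos(pi * nu))^(alpha + 1) * sqrt(A1 / A2)
  Hs <- H[((0:(M - 1)) + M / 2) %% M + 1]
  G <- exp(-2i * pi * nu) * Hs
  list(H = H, G = G)
}

fft_down <- function(Y) {
  M <- length(Y)
  (Y[1:(M / 2)] + Y[(M / 2 + 1):M]) / 2
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L

#' Build a fractional spline wavelet basis
#'
#' Constructs the frequency-sampled analysis/synthesis filter bank of an
#' orthonormal symmetric fractional spline wavelet of regularity `alpha`,
#' for epochs of dyadic length `N`. The basis is orthonormal (L2-normalized
#' atoms), so analysis/synthesis is a perfect-reconstruction round trip and
#' coefficient energy accounts exactly for signal energy.
#'
#' @param alpha Regularity (order) of the wavelet, a non-negative real;
#'   fractional values are allowed. `alpha = 0` gives the least regular
#'   (Haar-like) member of the family.
#' @param N Epoch length in samples; must be a power of two (see
#'   [extract_rhythmic()] for the padding policy applied to raw epochs).
#' @param J Number of dyadic scales for which filters are prepared
#'   (default `log2(N) - 1`, the deepest admissible decomposition).
#'
#' @return An object of class `wavelet_basis` with elements `alpha`, `N`,
#'   `J`, `filters` (per-level low/high-pass DFT responses) and `f0`, the
#'   characteristic mother-wavelet frequency such that scale `j` is centred
#'   at `f_j = 2^-j * f0 * fs` for sampling rate `fs`.
#' @seealso [wavedec()], [waverec()]
#' @export
#' @examples
#' b <- build_basis(4, 1024)
#' x <- rnorm(1024)
#' d <- wavedec(x, b, J = 8)
#' max(abs(waverec(d, b) - x))
build_basis <- function(alpha, N, J = log2(N) - 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative finite number", call. = FALSE)
  }
  key <- sprintf("%.12g_%d_%d", alpha, as.integer(N), as.integer(J))
  cached <- .basis_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (!is_pow2(N)) {
    stop("`N` must be a power of two; detrend and zero-pad the epoch ",
         "symmetrically to the next power of two (the policy applied by ",
         "extract_rhythmic()) before building a basis", call. = FALSE)
  }
  J <- as.integer(J)
  if (J < 1L || N < 2^(J + 1)) {
    stop("`J` must satisfy 1 <= J <= log2(N) - 1", call. = FALSE)
  }
  filters <- vector("list", J)
  M <- as.integer(N)
  for (l in seq_len(J)) {
    filters[[l]] <- fs_filters(alpha, M)
    M <- M %/% 2L
  }
  basis <- structure(
    list(alpha = alpha, N = as.integer(N), J = J, filters = filters, f0 = NA_real_),
    class = "wavelet_basis"
  )
  basis$f0 <- basis_f0(basis)
  if (length(ls(.basis_cache)) > 50L) {
    rm(list = ls(.basis_cache), envir = .basis_cache)
  }
  .basis_cache[[key]] <- basis
  basis
}

# Memo cache for filter banks; adapted orders vary per epoch, so the cache
# is cleared wholesale when it grows, keeping the frequently reused default
# orders cheap without unbounded growth.
.basis_cache <- new.env(parent = emptyenv())

# Characteristic mother frequency: spectral peak of the scale-1 atom,
# expressed so that f_j = 2^-j * f0 * fs. Computed numerically once per basis.
basis_f0 <- function(basis) {
  N <- basis$N
  w1 <- lapply(seq_len(basis$J), function(l) numeric(N / 2^l))
  w1[[1]][length(w1[[1]]) %/% 2] <- 1
  atom <- waverec(new_decomp(w1, numeric(N / 2^basis$J), N, fs = 1,
                             alpha = basis$alpha),
                  basis, include_residue = FALSE)
  spec <- Mod(stats::fft(atom))[seq_len(N / 2 + 1)]
  peak_cyc_per_sample <- (which.max(spec) - 1) / N
  2 * peak_cyc_per_sample
}

#' @export
print.wavelet_basis <- function(x, ...) {
  cat(sprintf(
    "Orthonormal fractional spline wavelet basis\n  alpha = %.4g, N = %d, J = %d, f0 = %.4g (x fs Hz at scale 0)\n",
    x$alpha, x$N, x$J, x$f0))
  invisible(x)
}

new_decomp <- function(coefficients, residue, N, fs, alpha) {
  structure(
    list(coefficients = coefficients, residue = residue,
         N = as.integer(N), fs = fs, alpha = alpha),
    class = "timescale_decomp"
  )
}

#' @export
print.timescale_decomp <- function(x, ...) {
  cat(sprintf("Timescale decomposition: N = %d, fs = %g Hz, alpha = %.4g\n",
              x$N, x$fs, x$alpha))
  cat(sprintf("  scales 1..%d with n_j = %s coefficients; residue length %d\n",
              length(x$coefficients),
              paste(vapply(x$coefficients, length, 1L), collapse = ", "),
              length(x$residue)))
  invisible(x)
}

#' Dyadic timescale decomposition of an epoch
#'
#' Expands a signal on dyadically scaled, time-shifted wavelet atoms:
#' scale `j` holds `n_j = 2^-j * N` coefficients, and the low-frequency
#' approximation not captured by scales `1..J` is returned as the residue.
#' The transform is orthonormal: coefficient energy plus residue energy
#' equals signal energy.
#'
#' @param x Numeric vector of length `basis$N`; all values must be finite.
#' @param basis A [build_basis()] object.
#' @param J Deepest scale to compute, `J <= log2(N) - 1` (default: the
#'   number of scales the basis was built for).
#' @param fs Sampling rate in Hz (stored for the scale-to-frequency map).
#'
#' @return A `timescale_decomp` with `coefficients` (list of per-scale
#'   vectors `w_jk`), `residue`, `N`, `fs`, `alpha`.
#' @export
wavedec <- function(x, basis, J = basis$J, fs = 1) {
  stopifnot(inherits(basis, "wavelet_basis"))
  if (length(x) != basis$N) {
    stop("signal length does not match basis N", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("signal contains NaN/Inf samples", call. = FALSE)
  }
  J <- as.integer(J)
  if (J > basis$J || J > log2(basis$N) - 1) {
    stop("`J` exceeds the admissible number of scales for this basis",
         call. = FALSE)
  }
  c0 <- as.numeric(x)
  w <- vector("list", J)
  for (l in seq_len(J)) {
    f <- basis$filters[[l]]
    M <- length(c0)
    C <- stats::fft(c0)
    w[[l]] <- Re(stats::fft(fft_down(Conj(f$G) * C), inverse = TRUE)) / (M / 2)
    c0 <- Re(stats::fft(fft_down(Conj(f$H) * C), inverse = TRUE)) / (M / 2)
  }
  new_decomp(w, c0, basis$N, fs, basis$alpha)
}

#' Synthesize a signal from a timescale decomposition
#'
#' Inverse of [wavedec()]. With unmodified coefficients and
#' `include_residue = TRUE` the original signal is reconstructed to
#' numerical precision; with `include_residue = FALSE` the slow
#' approximation `s_r` is omitted, which is how the rhythmic series is
#' synthesized (drifts and ultraslow activity live in the residue).
#'
#' @param decomp A `timescale_decomp`.
#' @param basis A [build_basis()] object sharing `N` with `decomp`. The
#'   basis order need not equal the analysis order: synthesizing in a
#'   different-order basis is what implements the fractional
#'   smoothness adjustment of the rhythmic synthesis.
#' @param include_residue Include the low-frequency residue? Default `TRUE`.
#'
#' @return Numeric vector of length `N`.
#' @export
waverec <- function(decomp, basis, include_residue = TRUE) {
  stopifnot(inherits(decomp, "timescale_decomp"), inherits(basis, "wavelet_basis"))
  J <- length(decomp$coefficients)
  if (decomp$N != basis$N || J > basis$J) {
    stop("decomposition and basis shapes do not match", call. = FALSE)
  }
  expected_res <- basis$N / 2^J
  if (length(decomp$residue) != expected_res) {
    stop("residue length does not match the decomposition depth", call. = FALSE)
  }
  c0 <- if (include_residue) decomp$residue else numeric(expected_res)
  for (l in rev(seq_len(J))) {
    f <- basis$filters[[l]]
    M <- 2L * length(c0)
    C <- f$H * rep(stats::fft(c0), 2) +
         f$G * rep(stats::fft(decomp$coefficients[[l]]), 2)
    c0 <- Re(stats::fft(C, inverse = TRUE)) / M
  }
  c0
}

#' Per-scale average log2 wavelet power
#'
#' `D_j = log2(mean_k w_jk^2)`, the summary on which the scaling-exponent
#' fit operates. A scale with all-zero coefficients yields `-Inf` with a
#' warning rather than an error, so degenerate (e.g. all-zero) epochs
#' propagate a recognizable sentinel.
#'
#' @param decomp A `timescale_decomp`.
#' @return Numeric vector `D_j`, one value per scale `j = 1..J`.
#' @export
scale_log_power <- function(decomp) {
  stopifnot(inherits(decomp, "timescale_decomp"))
  D <- vapply(decomp$coefficients, function(w) log2(mean(w^2)), numeric(1))
  if (any(!is.finite(D))) {
    warning("one or more scales have zero power; D_j = -Inf returned",
            call. = FALSE)
  }
  D
}

#' Scale-to-frequency map of a decomposition
#'
#' Centre frequency `f_j = 2^-j * f0 * fs` of each dyadic scale, strictly
#' decreasing in `j`.
#'
#' @param decomp A `timescale_decomp`.
#' @param basis The basis used for analysis (provides `f0`).
#' @return Numeric vector of per-scale centre frequencies in Hz.
#' @export
scale_frequencies <- function(decomp, basis) {
  stopifnot(inherits(decomp, "timescale_decomp"), inherits(basis, "wavelet_basis"))
  2^(-seq_along(decomp$coefficients)) * basis$f0 * decomp$fs
}
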
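#' Spectral analysis context for windowed rate estimation
#'
#' Bundles the constants every spectral stage shares: the window length
#' `N = window_s * rate_hz` samples (72), the zero-padded DFT length
#' `Nz = pad_factor * N` (8640), the half-grid frequencies
#' `f_k = k / (Nz * Ts)` for `k = 0 .. Nz/2 - 1`, and the respiration
#' band `[lim1, lim2]` = [0.5, 1.83] Hz (30–110 breaths/min).
#'
#' @param rate_hz uniform sampling rate (default 9 Hz).
#' @param window_s window length in seconds (default 8).
#' @param pad_factor zero-padding multiple of N (default 120).
#' @param lim1,lim2 respiration band edges in Hz.
#' @return A `spectral_context` list with elements `rate_hz`, `ts`, `n`,
#'   `nz`, `freqs`, `lim1`, `lim2`, `band` (logical mask on `freqs`).
#' @examples
#' ctx <- spectral_context()
#' ctx$n   # 72
#' ctx$nz  # 8640
#' @export
spectral_context <- function(rate_hz = 9, window_s = 8, pad_factor = 120,
                             lim1 = 0.5, lim2 = 1.83) {
  n <- as.integer(round(rate_hz * window_s))
  if (n < 4L) stop("window too short for spectral analysis")
  nz <- as.integer(pad_factor * n)
  ts <- 1 / rate_hz
  k <- 0:(nz %/% 2L - 1L)
  freqs <- k / (nz * ts)
  if (!(lim1 < lim2 && lim2 < rate_hz / 2))
    stop("need lim1 < lim2 < Nyquist")
  structure(list(rate_hz = rate_hz, ts = ts, n = n, nz = nz,
                 freqs = freqs, lim1 = lim1, lim2 = lim2,
                 band = freqs > lim1 & freqs < lim2),
            class = "spectral_context")
}

# symmetric Hanning window, zero endpoints (MATLAB hann(L))
hanning_window <- function(len) {
  if (len == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(len - 1L)) / (len - 1L)))
}

#' Magnitude spectra of pixel time series
#'
#' Columns of `series` (one pixel each) are optionally first-differenced
#' (the differential filter attenuating low frequencies), multiplied by a
#' symmetric Hanning window of their own length, zero-padded to `ctx$nz`
#' and transformed; magnitudes on the half grid are returned. Filtered
#' and unfiltered spectra are padded to the same `Nz` so their bins
#' align.
#'
#' @param series numeric matrix `N x n_pixels` (or a vector for one
#'   pixel).
#' @param ctx a [spectral_context()].
#' @param differential apply the first-difference filter first?
#' @param block pixels per FFT block, bounds peak memory.
#' @return Matrix `length(ctx$freqs) x n_pixels` of spectral magnitudes.
#' @export
pixel_spectra <- function(series, ctx, differential = TRUE, block = 2048L) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  n <- nrow(series)
  if (n < 4L) stop("need at least 4 samples per pixel")
  if (differential) {
    series <- series[-1L, , drop = FALSE] - series[-n, , drop = FALSE]
    n <- n - 1L
  }
  win <- hanning_window(n)
  npx <- ncol(series)
  half <- length(ctx$freqs)
  out <- matrix(0, half, npx)
  for (b0 in seq.int(1L, npx, by = block)) {
    b1 <- min(b0 + block - 1L, npx)
    padded <- matrix(0, ctx$nz, b1 - b0 + 1L)
    padded[seq_len(n), ] <- series[, b0:b1, drop = FALSE] * win
    out[, b0:b1] <- Mod(stats::mvfft(padded))[seq_len(half), , drop = FALSE]
  }
  out
}

# |H(f)|^2 of an analog Butterworth band-pass of order `order` between
# f_lo and f_hi; the zero-phase gain that forward-backward filtering
# with the order-`order` filter would realize.
butterworth_bp_gain2 <- function(f, f_lo, f_hi, order = 4L) {
  g <- numeric(length(f))
  nz <- f != 0
  x <- (f[nz]^2 - f_lo * f_hi) / (f[nz] * (f_hi - f_lo))
  g[nz] <- 1 / (1 + x^(2 * order))
  g
}

#' Zero-phase Butterworth band-pass of pixel time series
#'
#' Applies the squared magnitude response of an order-4 Butterworth
#' band-pass between `ctx$lim1` and `ctx$lim2` in the frequency domain:
#' the transfer function realized by forward-backward (zero-phase)
#' filtering, without edge transients, which matter on 72-sample
#' windows. The series mean (DC) is removed by the band-pass itself.
#'
#' @param series numeric matrix `N x n_pixels` (or vector).
#' @param ctx a [spectral_context()].
#' @param order Butterworth order (default 4).
#' @return Filtered series, same shape as the input.
#' @export
bandpass_series <- function(series, ctx, order = 4L) {
  vec_in <- is.null(dim(series))
  if (vec_in) series <- matrix(series, ncol = 1L)
  n <- nrow(series)
  f <- c(0, seq_len(n - 1L)) * ctx$rate_hz / n
  f <- pmin(f, ctx$rate_hz - f)            # two-sided |frequency|
  gain <- butterworth_bp_gain2(f, ctx$lim1, ctx$lim2, order)
  out <- Re(stats::mvfft(stats::mvfft(series) * gain, inverse = TRUE)) / n
  if (vec_in) out[, 1L] else out
}

#' Spectral peak of a single series, in breaths per minute
#'
#' Hanning window, zero-pad to `ctx$nz`, and return 60 times the
#' frequency of the magnitude-spectrum argmax within the respiration
#' band (ties: lowest frequency). Shared by the video and the reference
#' paths.
#'
#' @param series numeric vector of `ctx$n` samples.
#' @param ctx a [spectral_context()].
#' @param spectrum also return the band magnitudes?
#' @return If `spectrum = FALSE`, the peak rate in BPM (`NA` if the band
#'   spectrum is identically zero). Otherwise a list with `bpm` and
#'   `spectrum` (band magnitudes, named by frequency).
#' @export
spectral_peak_bpm <- function(series, ctx, spectrum = FALSE) {
  mag <- pixel_spectra(series, ctx, differential = FALSE)[, 1L]
  inband <- ctx$band
  m <- mag[inband]
  f <- ctx$freqs[inband]
  bpm <- if (max(m) <= 0) NA_real_ else 60 * f[which.max(m)]
  if (!spectrum) return(bpm)
  list(bpm = bpm, spectrum = stats::setNames(m, format(f, digits = 6)))
}
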
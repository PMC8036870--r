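# Independent oracles and fixture builders. Everything here is written
# to be dumb and obviously correct: plain loops and direct summation,
# no reuse of the package's computational paths.

# naive DFT magnitude of the Hanning-windowed, zero-padded series at
# arbitrary frequencies: |sum_n w_n x_n exp(-2 pi i f n Ts)|
naive_dft_mag <- function(x, freqs, ts) {
  n <- length(x)
  w <- if (n == 1L) 1 else 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
  xw <- x * w
  vapply(freqs, function(f) {
    Mod(sum(xw * exp(-2i * pi * f * (0:(n - 1L)) * ts)))
  }, numeric(1L))
}

# brute-force per-point linear interpolation of (tx, y) at time t
interp_point <- function(tx, y, t) {
  if (t <= tx[1L]) return(y[1L])
  if (t >= tx[length(tx)]) return(y[length(y)])
  i <- max(which(tx <= t))
  if (tx[i] == t) return(y[i])
  y[i] + (y[i + 1L] - y[i]) * (t - tx[i]) / (tx[i + 1L] - tx[i])
}

# window_view from a frames array with defaults for bookkeeping fields
make_window <- function(frames, rate_hz = 9, start_s = 0, index = 1L) {
  window_view(frames, start_s = start_s, rate_hz = rate_hz,
              window_index = index)
}

# constant-background window carrying given per-pixel time series:
# series is an N x k matrix, positions a k x 2 matrix of (row, col)
window_with_series <- function(series, positions, rows, cols,
                               background = 0) {
  n <- nrow(series)
  x <- array(background, c(n, rows, cols))
  for (k in seq_len(ncol(series)))
    x[, positions[k, 1L], positions[k, 2L]] <- series[, k]
  make_window(x)
}

# exhaustive moving-pixel/classification oracle: plain loops over
# frames and pixels, one view
oracle_classify_view <- function(frames, f1, thr2) {
  nt <- dim(frames)[1L]
  rng <- max(frames) - min(frames)
  thr1 <- rng / f1
  npx <- prod(dim(frames)[2:3])
  for (u in seq_len(nt - 1L)) {
    cnt <- 0L
    for (r in seq_len(dim(frames)[2L])) for (cc in seq_len(dim(frames)[3L])) {
      if (abs(frames[u + 1L, r, cc] - frames[u, r, cc]) > thr1)
        cnt <- cnt + 1L
    }
    if (cnt / npx >= thr2) return(1L)
  }
  0L
}

# default 24x32 still breathing scene used across tests (small enough
# that one window's feature maps compute in under a second)
still_scene <- function(rr_bpm = 40, seed = 1, duration_s = 20,
                        noise_sd = 0.05, harmonic = 0, events = NULL) {
  scene_spec(rows = 24L, cols = 32L, duration_s = duration_s,
             noise_sd = noise_sd,
             cluster = list(rows = 8:16, cols = 10:22, rr_bpm = rr_bpm,
                            amplitude = 0.3, harmonic = harmonic,
                            edge_offset = 2),
             events = events, seed = seed)
}
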
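#' Correlation-based selection of respiration pixels
#'
#' Every pixel's series is band-pass filtered to the respiration band
#' and correlated (Pearson) with the core pixel's filtered series;
#' pixels with `|c| > kappa3` are members (anti-phase pixels, e.g. the
#' two sides of a moving edge, count via the absolute value). The
#' threshold of 0.9 is deliberately strict because correlation estimated
#' on 72 samples is noisy. Zero-variance filtered series have undefined
#' correlation and are excluded.
#'
#' @param window a [window_view()] (merged plane).
#' @param core integer `c(row, col)` of the core pixel.
#' @param ctx a [spectral_context()].
#' @param kappa3 correlation threshold (default 0.9, strict `>`).
#' @return List: `core`, `members` (matrix of row, col), `correlations`
#'   (per member, signed), `series` (filtered member series, one column
#'   each, sign-aligned with the core).
#' @export
select_pixels <- function(window, core, ctx, kappa3 = 0.9) {
  stopifnot(inherits(window, "window_view"), length(core) == 2L)
  d <- dim(window$frames)
  flat <- matrix(window$frames, nrow = d[1L])
  filt <- bandpass_series(flat, ctx)
  core_idx <- (core[2L] - 1L) * d[2L] + core[1L]
  core_series <- filt[, core_idx]
  if (stats::sd(core_series) == 0)
    return(list(core = core, members = matrix(integer(0), 0, 2L),
                correlations = numeric(0), series = NULL))
  v <- colMeans(filt^2) - colMeans(filt)^2
  ok <- is.finite(v) & v > 1e-24
  cc <- rep(NA_real_, ncol(filt))
  cc[ok] <- as.vector(stats::cor(core_series, filt[, ok, drop = FALSE]))
  member <- !is.na(cc) & abs(cc) > kappa3
  idx <- which(member)
  members <- cbind(row = (idx - 1L) %% d[2L] + 1L,
                   col = (idx - 1L) %/% d[2L] + 1L)
  # sign-align anti-phase members so averaging is constructive
  series <- sweep(filt[, idx, drop = FALSE], 2L, sign(cc[idx]), `*`)
  list(core = core, members = members, correlations = cc[idx],
       series = series)
}

#' Respiration rate of one window from its selected pixels
#'
#' The filtered member series are averaged into one respiratory signal,
#' Hanning-windowed, zero-padded to `Nz` and transformed; the rate is
#' 60 times the in-band spectral peak frequency.
#'
#' @param selection result of [select_pixels()].
#' @param ctx a [spectral_context()].
#' @return List: `rr_bpm` (NA if the selection is empty or the band
#'   spectrum is zero), `n_pixels`, `signal` (averaged series),
#'   `spectrum` (in-band magnitudes).
#' @export
estimate_rr <- function(selection, ctx) {
  if (is.null(selection$series) || ncol(selection$series) == 0L)
    return(list(rr_bpm = NA_real_, n_pixels = 0L, signal = NULL,
                spectrum = NULL))
  avg <- rowMeans(selection$series)
  pk <- spectral_peak_bpm(avg, ctx, spectrum = TRUE)
  list(rr_bpm = pk$bpm, n_pixels = nrow(selection$members),
       signal = avg, spectrum = pk$spectrum)
}

#' Feature maps of one window
#'
#' Computes the three per-pixel features over the (merged) frame grid:
#' pseudo-periodicity Q, dominant-frequency map RRhat and its 3x3
#' cluster score W, and the binary gradient map G, plus the fused map V
#' and core pixel. Pixels are processed in blocks to bound the memory
#' of the `Nz`-point spectra.
#'
#' @param window a [window_view()] (merged plane).
#' @param ctx a [spectral_context()].
#' @param kappa1,kappa2 cluster and gradient constants (defaults 70, 16).
#' @param block pixels per spectral block.
#' @return List: matrices `Q`, `RRhat`, `W`, `G`, `V`; `core`;
#'   `quality_ok`.
#' @export
window_feature_maps <- function(window, ctx, kappa1 = 70, kappa2 = 16,
                                block = 4096L) {
  stopifnot(inherits(window, "window_view"))
  d <- dim(window$frames)
  if (d[1L] != ctx$n)
    stop("window has ", d[1L], " samples but the context expects ", ctx$n)
  flat <- matrix(window$frames, nrow = d[1L])
  npx <- ncol(flat)
  q <- numeric(npx)
  rr <- numeric(npx)
  for (b0 in seq.int(1L, npx, by = block)) {
    b1 <- min(b0 + block - 1L, npx)
    cols <- b0:b1
    mag_filt <- pixel_spectra(flat[, cols, drop = FALSE], ctx,
                              differential = TRUE, block = block)
    mag_raw <- pixel_spectra(flat[, cols, drop = FALSE], ctx,
                             differential = FALSE, block = block)
    q[cols] <- pseudo_periodicity(mag_filt)
    rr[cols] <- dominant_frequency(mag_filt, mag_raw, ctx)
  }
  Q <- matrix(q, d[2L], d[3L])
  RRhat <- matrix(rr, d[2L], d[3L])
  W <- cluster_filter(RRhat, kappa1)
  G <- gradient_feature(window, kappa2)
  fused <- fuse_and_pick_core(Q, W, G)
  list(Q = Q, RRhat = RRhat, W = W, G = G, V = fused$V,
       core = fused$core, quality_ok = fused$quality_ok)
}

#' Estimate the respiration rate of one usable window
#'
#' Full single-window chain: feature maps, core pixel, correlation
#' selection, averaged signal, spectral peak.
#'
#' @inheritParams window_feature_maps
#' @param kappa3 correlation threshold for pixel selection.
#' @param keep_maps retain the feature maps in the result?
#' @return List: `rr_bpm`, `quality_ok`, `n_pixels`, `core` (or NULL),
#'   `spectrum` (in-band magnitudes or NULL), and `maps` if requested.
#' @export
window_rr <- function(window, ctx, kappa1 = 70, kappa2 = 16, kappa3 = 0.9,
                      block = 4096L, keep_maps = FALSE) {
  maps <- window_feature_maps(window, ctx, kappa1, kappa2, block)
  if (!maps$quality_ok) {
    out <- list(rr_bpm = NA_real_, quality_ok = FALSE, n_pixels = 0L,
                core = NULL, spectrum = NULL)
    if (keep_maps) out$maps <- maps
    return(out)
  }
  sel <- select_pixels(window, maps$core, ctx, kappa3)
  est <- estimate_rr(sel, ctx)
  out <- list(rr_bpm = est$rr_bpm,
              quality_ok = !is.na(est$rr_bpm),
              n_pixels = est$n_pixels,
              core = maps$core,
              spectrum = est$spectrum)
  if (keep_maps) out$maps <- maps
  out
}

#' Reference respiration rate from a chest-impedance-like waveform
#'
#' The waveform (typically 62.5 Hz) is linearly resampled to the video
#' rate and processed exactly like a one-pixel video: 8 s / 1 s sliding
#' windows, band-pass, Hanning, zero-pad, in-band spectral peak. A
#' window whose band spectrum is zero (e.g. a flat waveform) gets NA.
#'
#' @param waveform data.frame with `timestamp_s` and `value`.
#' @param ctx a [spectral_context()].
#' @param window_s,slide_s window geometry in seconds.
#' @return data.frame: `window_index`, `start_s`, `rr_ref_bpm`.
#' @export
reference_rr <- function(waveform, ctx, window_s = 8, slide_s = 1) {
  stopifnot(is.data.frame(waveform),
            all(c("timestamp_s", "value") %in% names(waveform)))
  stack <- frame_stack(array(waveform$value,
                             c(length(waveform$value), 1L, 1L)),
                       waveform$timestamp_s)
  windows <- window_stack(stack, rate_hz = ctx$rate_hz,
                          window_s = window_s, slide_s = slide_s)
  if (length(windows) == 0L)
    return(data.frame(window_index = integer(0), start_s = numeric(0),
                      rr_ref_bpm = numeric(0)))
  rows <- lapply(windows, function(w) {
    filt <- bandpass_series(as.vector(w$frames), ctx)
    data.frame(window_index = w$window_index, start_s = w$start_s,
               rr_ref_bpm = spectral_peak_bpm(filt, ctx))
  })
  do.call(rbind, rows)
}

#' Assemble per-window spectra into a short-time Fourier transform
#'
#' Rows are windows in temporal order (by global window index, so gaps
#' in the recording appear as missing rows), columns are in-band
#' frequency bins. Windows without a spectrum (type-1 motion, excluded,
#' low quality) are rows of NA.
#'
#' @param window_index integer vector of global window indices.
#' @param spectra list of in-band magnitude vectors (NULL where absent),
#'   parallel to `window_index`.
#' @param ctx a [spectral_context()].
#' @return Numeric matrix `max(window_index) x n_band_bins` with
#'   attribute `freqs_hz`; class `rr_stft`.
#' @export
build_stft <- function(window_index, spectra, ctx) {
  stopifnot(length(window_index) == length(spectra))
  nb <- sum(ctx$band)
  nr <- if (length(window_index)) max(window_index) else 0L
  m <- matrix(NA_real_, nr, nb)
  for (i in seq_along(spectra)) {
    if (!is.null(spectra[[i]]))
      m[window_index[i], ] <- as.numeric(spectra[[i]])
  }
  attr(m, "freqs_hz") <- ctx$freqs[ctx$band]
  class(m) <- c("rr_stft", class(m))
  m
}

#' @export
print.rr_stft <- function(x, ...) {
  cat(sprintf("<rr_stft> %d windows x %d bins (%.3f-%.3f Hz), %d empty rows\n",
              nrow(x), ncol(x), attr(x, "freqs_hz")[1L],
              attr(x, "freqs_hz")[ncol(x)], sum(!stats::complete.cases(x))))
  invisible(x)
}

#' Per-window respiration-rate track for a recording
#'
#' Runs motion gating and rate estimation over aligned window sets: a
#' window flagged as type-1 motion never receives a rate. When a
#' merged-plane window list is given separately from the per-view lists
#' used by the detector, motion is detected per view and the rate is
#' estimated on the merged plane.
#'
#' @param window_sets list of per-window view-lists (or single windows)
#'   for motion detection.
#' @param merged_windows list of merged-plane [window_view()]s, parallel
#'   to `window_sets` (defaults to merging each set's views rowwise).
#' @param ctx a [spectral_context()].
#' @param params a [motion_params()].
#' @param kappa1,kappa2,kappa3 feature constants.
#' @return List: `track` (data.frame with window_index, start_s,
#'   rr_video_bpm, motion_flag, quality_flag, n_selected_pixels,
#'   core_row, core_col, max_ratio), `stft` (an `rr_stft`).
#' @export
rr_track <- function(window_sets, merged_windows = NULL, ctx,
                     params = motion_params(),
                     kappa1 = 70, kappa2 = 16, kappa3 = 0.9) {
  if (is.null(merged_windows)) {
    merged_windows <- lapply(window_sets, function(w) {
      views <- if (inherits(w, "window_view")) list(w) else w
      if (length(views) == 1L) return(views[[1L]])
      merged <- do.call(abind_rows, lapply(views, `[[`, "frames"))
      window_view(merged, views[[1L]]$start_s, views[[1L]]$rate_hz,
                  views[[1L]]$window_index, views[[1L]]$view_id)
    })
  }
  motion <- detect_motion(window_sets, params)
  rows <- vector("list", length(merged_windows))
  spectra <- vector("list", length(merged_windows))
  for (i in seq_along(merged_windows)) {
    w <- merged_windows[[i]]
    if (motion$motion_flag[i] == 1L) {
      rows[[i]] <- data.frame(
        window_index = w$window_index, start_s = w$start_s,
        rr_video_bpm = NA_real_, motion_flag = 1L, quality_flag = 0L,
        n_selected_pixels = 0L, core_row = NA_integer_,
        core_col = NA_integer_, max_ratio = motion$max_ratio[i])
      next
    }
    est <- window_rr(w, ctx, kappa1, kappa2, kappa3)
    spectra[[i]] <- est$spectrum
    rows[[i]] <- data.frame(
      window_index = w$window_index, start_s = w$start_s,
      rr_video_bpm = est$rr_bpm, motion_flag = 0L,
      quality_flag = as.integer(!est$quality_ok),
      n_selected_pixels = est$n_pixels,
      core_row = if (is.null(est$core)) NA_integer_ else est$core[1L],
      core_col = if (is.null(est$core)) NA_integer_ else est$core[2L],
      max_ratio = motion$max_ratio[i])
  }
  track <- do.call(rbind, rows)
  stft <- build_stft(track$window_index, spectra, ctx)
  list(track = track, stft = stft)
}

# stack 3-D arrays along the row (second) dimension
abind_rows <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  rows <- vapply(arrs, function(a) dim(a)[2L], integer(1L))
  out <- array(0, c(d[1L], sum(rows), d[3L]))
  at <- 0L
  for (a in arrs) {
    out[, at + seq_len(dim(a)[2L]), ] <- a
    at <- at + dim(a)[2L]
  }
  out
}
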
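ctx <- spectral_context()

test_that("spectral_context carries the analytic constants", {
  expect_equal(ctx$n, 72L)
  expect_equal(ctx$nz, 120L * 72L)
  expect_equal(ctx$ts, 1 / 9)
  expect_equal(length(ctx$freqs), ctx$nz / 2)
  expect_equal(ctx$freqs[2] - ctx$freqs[1], 1 / (ctx$nz * ctx$ts))
  expect_error(spectral_context(lim1 = 2, lim2 = 1.83), "lim1")
})

test_that("pixel_spectra matches a naive DFT-summation oracle", {
  t <- (0:71) / 9
  # constant pixel: differential series all zero -> flat zero spectrum
  expect_true(all(pixel_spectra(rep(3, 72), ctx, TRUE) == 0))
  # DC pixel without the differential filter: energy concentrated at
  # k = 0 (the Hanning window spreads a mainlobe of ~1/(N Ts) around
  # DC; beyond it the spectrum collapses)
  mag <- pixel_spectra(rep(3, 72), ctx, FALSE)
  expect_equal(which.max(mag), 1L)
  expect_true(all(mag[ctx$freqs > 1] < mag[1] * 1e-2))

  # 0.667 Hz unit sinusoid: argmax within one grid bin of 0.667 Hz and
  # magnitudes equal to the naive windowed-DFT oracle
  x <- sin(2 * pi * 0.667 * t)
  mag <- pixel_spectra(x, ctx, FALSE)[, 1]
  kmax <- which.max(mag)
  expect_lte(abs(ctx$freqs[kmax] - 0.667), 1 / (ctx$nz * ctx$ts))
  probe <- c(1, kmax - 1, kmax, kmax + 1, 2000)
  expect_equal(mag[probe], naive_dft_mag(x, ctx$freqs[probe], ctx$ts),
               tolerance = 1e-9)
  # differential path: oracle applied to the hand-differenced series
  magf <- pixel_spectra(x, ctx, TRUE)[, 1]
  expect_equal(magf[probe], naive_dft_mag(diff(x), ctx$freqs[probe], ctx$ts),
               tolerance = 1e-9)
  expect_error(pixel_spectra(c(1, 2, 3), ctx), "at least 4")
})

test_that("pseudo_periodicity is the normalized spectral peak height", {
  # single nonzero bin -> q = 1; two equal bins -> 1/sqrt(2)
  spec1 <- c(rep(0, 10), 5, rep(0, 9))
  expect_equal(pseudo_periodicity(spec1), 1)
  spec2 <- c(rep(0, 5), 3, rep(0, 5), 3, rep(0, 8))
  expect_equal(pseudo_periodicity(spec2), 1 / sqrt(2))
  expect_equal(pseudo_periodicity(rep(0, 20)), 0)

  # sinusoid beats white noise, over 100 seeded draws
  t <- (0:71) / 9
  wins <- 0L
  for (s in 1:100) {
    set.seed(s)
    q_noise <- pseudo_periodicity(pixel_spectra(rnorm(72), ctx))
    q_sin <- pseudo_periodicity(
      pixel_spectra(sin(2 * pi * 0.7 * t + runif(1, 0, 2 * pi)), ctx))
    wins <- wins + (q_sin > q_noise)
  }
  expect_equal(wins, 100L)
  # q is bounded by 1
  set.seed(1)
  expect_lte(max(pseudo_periodicity(
    pixel_spectra(matrix(rnorm(72 * 20), 72), ctx))), 1)
})

test_that("dominant_frequency disambiguates the first harmonic", {
  t <- (0:71) / 9
  tol <- 1 / (ctx$n * ctx$ts)
  # fundamental 0.6 Hz + strong first harmonic: differentiation makes
  # 1.2 Hz dominate y' while y keeps 0.6 Hz dominant -> 0.6 returned
  x <- sin(2 * pi * 0.6 * t) + 0.6 * sin(2 * pi * 1.2 * t)
  mf <- pixel_spectra(x, ctx, TRUE)
  mr <- pixel_spectra(x, ctx, FALSE)
  expect_lt(abs(ctx$freqs[which.max(mf)] - 1.2), 0.05)  # y' peak = harmonic
  expect_lt(abs(ctx$freqs[which.max(mr)] - 0.6), 0.05)  # y peak = fundamental
  rr <- dominant_frequency(mf, mr, ctx)
  expect_lt(abs(rr - 0.6), tol)

  # fast NNS-like oscillation: suppressed to zero
  x <- 0.3 * sin(2 * pi * 2.5 * t)
  rr <- dominant_frequency(pixel_spectra(x, ctx, TRUE),
                           pixel_spectra(x, ctx, FALSE), ctx)
  expect_equal(rr, 0)

  # clean in-band sinusoid, no harmonic: nearest grid frequency,
  # cross-checked against the naive DFT argmax oracle
  x <- sin(2 * pi * 1.0 * t)
  mf <- pixel_spectra(x, ctx, TRUE)
  rr <- dominant_frequency(mf, pixel_spectra(x, ctx, FALSE), ctx)
  band_idx <- which(ctx$band)
  oracle <- naive_dft_mag(diff(x), ctx$freqs[band_idx], ctx$ts)
  expect_equal(rr, ctx$freqs[band_idx[which.max(oracle)]])
  expect_lte(abs(rr - 1.0), 1 / (ctx$nz * ctx$ts))
})

test_that("cluster_filter rewards frequency-coherent neighborhoods", {
  # uniform patch: center weight exactly 1
  w <- cluster_filter(matrix(0.7, 3, 3))
  expect_equal(w[2, 2], 1)
  # suppressed center (rr = 0) never clusters
  m <- matrix(0.7, 3, 3); m[2, 2] <- 0
  expect_equal(cluster_filter(m)[2, 2], 0)
  # hand evaluation: center 0.7, eight neighbors 0.8
  m <- matrix(0.8, 3, 3); m[2, 2] <- 0.7
  expect_equal(cluster_filter(m)[2, 2],
               (1 + 8 * exp(-70 * 0.1 / 0.7)) / 9, tolerance = 1e-12)
  # borders are zero
  w <- cluster_filter(matrix(0.7, 5, 5))
  expect_true(all(w[c(1, 5), ] == 0) && all(w[, c(1, 5)] == 0))
  expect_equal(w[3, 3], 1)
})

test_that("gradient_feature thresholds edges at Range/kappa2", {
  # constant window: G identically zero
  expect_true(all(gradient_feature(make_window(array(4, c(6, 8, 9)))) == 0))

  # vertical step of the full window range: flagged along the edge
  img <- matrix(0, 10, 12); img[6:10, ] <- 1
  w <- make_window(array(rep(img, each = 6), c(6, 10, 12)))
  g <- gradient_feature(w)
  expect_true(all(g[5:6, ] == 1))          # rows adjacent to the step
  expect_true(all(g[c(1:3, 8:10), ] == 0)) # far from it

  # smooth ramp with slope Range/100 per pixel: below Range/16
  img <- matrix(rep(seq(0, 0.09, length.out = 10), 12), 10, 12)
  base <- array(rep(img, each = 6), c(6, 10, 12))
  base[1, 1, 1] <- 1                       # pins the window range to ~1
  g <- gradient_feature(make_window(base))
  expect_true(all(g[3:10, 3:12] == 0))
})

test_that("fuse_and_pick_core multiplies normalized maps with veto", {
  set.seed(12)
  Q <- matrix(runif(20, 0.2, 0.8), 4, 5)
  W <- matrix(runif(20, 0.2, 0.8), 4, 5)
  G <- matrix(1, 4, 5)
  G[4, 5] <- 0                             # G must not be constant
  Q[2, 3] <- 1; W[2, 3] <- 1               # maximal in all maps
  out <- fuse_and_pick_core(Q, W, G)
  expect_equal(unname(out$core), c(2L, 3L))
  expect_true(out$quality_ok)

  # zero in any one map vetoes the pixel
  G[2, 3] <- 0
  out <- fuse_and_pick_core(Q, W, G)
  expect_equal(out$V[2, 3], 0)
  expect_false(all(out$core == c(2, 3)))
  W2 <- W; W2[2, 3] <- 0
  G3 <- matrix(1, 4, 5); G3[4, 5] <- 0
  expect_equal(fuse_and_pick_core(Q, W2, G3)$V[2, 3], 0)

  # all-zero fused map flags low quality instead of erroring
  out <- fuse_and_pick_core(Q * 0, W, G)
  expect_false(out$quality_ok)
  expect_null(out$core)
})

test_that("select_pixels keeps |correlation| > 0.9 with the core", {
  t <- (0:71) / 9
  sig <- sin(2 * pi * 0.7 * t)
  set.seed(42)
  series <- cbind(core = sig,
                  anti = -sig,
                  noisy = sig + rnorm(72, sd = sqrt(10)),  # SNR 0.1
                  flat = rep(0, 72))
  w <- window_with_series(series, cbind(2:5, 2), rows = 6, cols = 4)
  sel <- select_pixels(w, core = c(2L, 2L), ctx)
  keyed <- apply(sel$members, 1, paste, collapse = ",")
  expect_true("2,2" %in% keyed)            # core correlates 1 with itself
  expect_true("3,2" %in% keyed)            # exact negative: |c| = 1
  expect_false("4,2" %in% keyed)           # SNR 0.1 never reaches 0.9
  expect_false("5,2" %in% keyed)           # zero variance excluded
  expect_equal(sel$correlations[keyed == "2,2"], 1)
  expect_equal(sel$correlations[keyed == "3,2"], -1, tolerance = 1e-9)

  # heavy independent noise stays excluded over seeded draws
  for (s in 1:20) {
    set.seed(s)
    series[, "noisy"] <- sig + rnorm(72, sd = sqrt(10))
    w <- window_with_series(series, cbind(2:5, 2), rows = 6, cols = 4)
    sel <- select_pixels(w, core = c(2L, 2L), ctx)
    expect_false("4,2" %in% apply(sel$members, 1, paste, collapse = ","))
  }
})

test_that("estimate_rr reads the peak of the averaged member spectrum", {
  t <- (0:71) / 9
  sig <- sin(2 * pi * 40 / 60 * t)         # 40 BPM
  w <- window_with_series(cbind(sig, sig, -sig), cbind(2:4, 2),
                          rows = 6, cols = 4)
  sel <- select_pixels(w, core = c(2L, 2L), ctx)
  est <- estimate_rr(sel, ctx)
  expect_equal(est$n_pixels, 3L)
  expect_lt(abs(est$rr_bpm - 40), 3.75)

  # oracle: 60 x argmax of a naive windowed DFT of the averaged series
  band_idx <- which(ctx$band)
  oracle <- naive_dft_mag(est$signal, ctx$freqs[band_idx], ctx$ts)
  expect_equal(est$rr_bpm, 60 * ctx$freqs[band_idx[which.max(oracle)]])

  # duplicated members do not change the estimate
  w2 <- window_with_series(cbind(sig, sig), cbind(2:3, 2), 6, 4)
  w1 <- window_with_series(cbind(sig), cbind(2, 2), 6, 4)
  r2 <- estimate_rr(select_pixels(w2, c(2L, 2L), ctx), ctx)
  r1 <- estimate_rr(select_pixels(w1, c(2L, 2L), ctx), ctx)
  expect_equal(r2$rr_bpm, r1$rr_bpm)

  # empty selection yields no rate
  empty <- list(series = NULL, members = matrix(integer(0), 0, 2))
  expect_true(is.na(estimate_rr(empty, ctx)$rr_bpm))
})

test_that("reference path equals a one-pixel video path", {
  set.seed(8)
  tt <- seq(0, 30, by = 1 / 62.5)
  wave <- data.frame(timestamp_s = tt,
                     value = sin(2 * pi * 50 / 60 * tt) +
                       rnorm(length(tt), sd = 0.05))
  ref <- reference_rr(wave, ctx)
  expect_gt(nrow(ref), 0)
  expect_true(all(abs(ref$rr_ref_bpm - 50) <= 1))

  # noiseless 50 BPM waveform: every window within one grid bin
  clean <- data.frame(timestamp_s = tt, value = sin(2 * pi * 50 / 60 * tt))
  ref_clean <- reference_rr(clean, ctx)
  expect_true(all(abs(ref_clean$rr_ref_bpm - 50) <=
                    60 / (ctx$nz * ctx$ts) + 1e-9))

  # same series pushed through the video windowing as a 1x1 video
  stack <- frame_stack(array(wave$value, c(length(tt), 1, 1)), tt)
  wins <- window_stack(stack)
  video_bpm <- vapply(wins, function(w)
    spectral_peak_bpm(bandpass_series(as.vector(w$frames), ctx), ctx),
    numeric(1))
  expect_equal(video_bpm, ref$rr_ref_bpm)

  # constant waveform: no valid peak, flagged as NA
  flat <- data.frame(timestamp_s = tt, value = 1)
  expect_true(all(is.na(reference_rr(flat, ctx)$rr_ref_bpm)))
})

test_that("build_stft arranges window spectra with gap bookkeeping", {
  nb <- sum(ctx$band)
  s1 <- runif(nb); s2 <- runif(nb)
  one <- build_stft(1L, list(s1), ctx)
  expect_equal(dim(one), c(1L, nb))
  expect_equal(one[1, ], s1)
  # gap-split indices leave NA rows; motion windows marked absent
  m <- build_stft(c(1L, 2L, 5L), list(s1, NULL, s2), ctx)
  expect_equal(nrow(m), 5L)
  expect_true(all(is.na(m[2, ])) && all(is.na(m[3, ])) && all(is.na(m[4, ])))
  expect_equal(m[5, ], s2)
  expect_equal(length(attr(m, "freqs_hz")), nb)
})

test_that("bandpass_series passes the band and kills DC and fast bands", {
  t <- (0:71) / 9
  inband <- sin(2 * pi * 1.0 * t)
  y <- bandpass_series(inband, ctx)
  expect_gt(stats::sd(y), 0.8 * stats::sd(inband))     # band preserved
  expect_lt(abs(mean(y)), 1e-10)                       # DC removed
  slow <- bandpass_series(rep(5, 72), ctx)
  expect_true(all(abs(slow) < 1e-10))
  fast <- bandpass_series(sin(2 * pi * 3.5 * t), ctx)
  expect_lt(stats::sd(fast), 0.05)                     # stop-band crushed
})
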
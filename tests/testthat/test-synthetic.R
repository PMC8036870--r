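test_that("generation is seeded and bit-deterministic", {
  spec <- still_scene(seed = 123)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$stacks[[1]]$frames, b$stacks[[1]]$frames)
  expect_identical(a$reference, b$reference)
  expect_identical(a$annotations, b$annotations)
  c <- generate_scene(still_scene(seed = 124))
  expect_false(identical(a$stacks[[1]]$frames, c$stacks[[1]]$frames))
})

test_that("noise-free event-free scene is constant off-cluster and
           single-peaked inside", {
  spec <- scene_spec(rows = 16, cols = 20, duration_s = 10, noise_sd = 0,
                     cluster = list(rows = 5:10, cols = 6:14, rr_bpm = 45,
                                    amplitude = 0.4, harmonic = 0,
                                    edge_offset = 2),
                     seed = 5)
  rec <- generate_scene(spec)
  x <- rec$stacks[[1]]$frames
  # outside the cluster every pixel is constant in time (the static
  # background structure varies across pixels, not across frames)
  outside <- x[, 1:4, , drop = FALSE]
  temporal_range <- apply(outside, c(2, 3), function(v) max(v) - min(v))
  expect_true(all(temporal_range == 0))
  # a cluster pixel has exactly one spectral peak, at the set rate
  ctx <- spectral_context()
  px <- x[1:72, 7, 10]
  mag <- pixel_spectra(px, ctx, differential = TRUE)[, 1]
  kmax <- which.max(mag)
  expect_lt(abs(ctx$freqs[kmax] - 45 / 60), 1 / (ctx$n * ctx$ts))
  # no secondary peak above 10% of the main one away from the carrier
  far <- abs(ctx$freqs - ctx$freqs[kmax]) > 0.35
  expect_lt(max(mag[far]), 0.1 * mag[kmax])
})

test_that("type-1 events are flagged by the motion detector by construction", {
  ev <- data.frame(type = "type1", start_s = 10, end_s = 14,
                   area_frac = 0.02, jump = 5)
  rec <- generate_scene(still_scene(seed = 9, duration_s = 25, events = ev))
  prep <- preprocess_views(rec$stacks)
  motion <- detect_motion(prep$window_sets, motion_params(8, 0.005))
  overlaps <- vapply(prep$merged_windows, function(w)
    w$start_s < 14 && w$start_s + 8 > 10, logical(1))
  expect_true(all(motion$motion_flag[overlaps] == 1L))
  expect_true(all(motion$motion_flag[!overlaps] == 0L))
})

test_that("annotations and event schedule are mutually derivable", {
  ev <- data.frame(type = c("type1", "type2", "nns", "excluded"),
                   start_s = c(3, 8, 12, 16),
                   end_s = c(5, 10, 15, 18),
                   row0 = c(NA, 1, 1, NA), row1 = c(NA, 5, 5, NA),
                   col0 = c(NA, 1, 1, NA), col1 = c(NA, 5, 5, NA))
  rec <- generate_scene(still_scene(seed = 2, events = ev))
  back <- schedule_from_annotations(rec$annotations)
  expect_equal(nrow(back), 4)
  expect_equal(sort(back$type), sort(ev$type))
  # frame quantization at 9 Hz: recovered bounds within one frame period
  m <- merge(back, ev, by = "type", suffixes = c("_rec", "_true"))
  expect_true(all(abs(m$start_s_rec - m$start_s_true) <= 1 / 9 + 1e-9))
  expect_true(all(abs(m$end_s_rec - m$end_s_true) <= 1 / 9 + 1e-9))
  # annotation flags agree with the schedule frame by frame
  ann <- rec$annotations
  on <- ann$timestamp_s >= 8 & ann$timestamp_s < 10
  expect_true(all(ann$type2[on] == 1) && all(ann$type2[!on] == 0))
})

test_that("ground-truth rate covers still windows at the cluster rate", {
  rec <- generate_scene(still_scene(rr_bpm = 55, seed = 3))
  expect_true(all(rec$truth$rr_true_bpm == 55))
  expect_true(all(rec$truth$event_free))
  ev <- data.frame(type = "type2", start_s = 5, end_s = 7,
                   row0 = 1, row1 = 4, col0 = 1, col1 = 4)
  rec2 <- generate_scene(still_scene(seed = 3, events = ev))
  marked <- rec2$truth$start_s < 7 & rec2$truth$start_s + 8 > 5
  expect_true(all(rec2$truth$event_free == !marked))
})

test_that("multi-view generation shares the schedule across views", {
  spec <- scene_spec(rows = 12, cols = 16, duration_s = 12,
                     cluster = list(rows = 4:8, cols = 5:11, rr_bpm = 40,
                                    amplitude = 0.3, harmonic = 0,
                                    edge_offset = 2),
                     seed = 6)
  rec <- make_multiview(spec, n_views = 3)
  expect_length(rec$stacks, 3)
  merged <- merge_views(rec$stacks)
  expect_equal(dim(merged$frames)[2:3], c(36L, 16L))
  # per-view noise is independent
  expect_false(identical(rec$stacks[[1]]$frames, rec$stacks[[2]]$frames))
  # n_views = 1 falls back to the single-view generator
  rec1 <- make_multiview(spec, n_views = 1)
  expect_identical(rec1$stacks[[1]]$frames,
                   generate_scene(spec)$stacks[[1]]$frames)
})

test_that("a type-1 event in one view still flags the window (view OR)", {
  ev <- data.frame(type = "type1", start_s = 4, end_s = 7,
                   area_frac = 0.03, jump = 5, view = 2L)
  spec <- scene_spec(rows = 12, cols = 16, duration_s = 16,
                     cluster = list(rows = 4:8, cols = 5:11, rr_bpm = 40,
                                    amplitude = 0.3, harmonic = 0,
                                    edge_offset = 2),
                     events = ev, seed = 13)
  rec <- make_multiview(spec, n_views = 3)
  prep <- preprocess_views(rec$stacks)
  motion <- detect_motion(prep$window_sets, motion_params(8, 0.005))
  overlaps <- vapply(prep$merged_windows, function(w)
    w$start_s < 7 && w$start_s + 8 > 4, logical(1))
  expect_true(all(motion$motion_flag[overlaps] == 1L))
  expect_true(all(motion$motion_flag[!overlaps] == 0L))
  # and the event is invisible in view 1 and 3's pixels
  m1 <- detect_motion(lapply(prep$window_sets, function(v) v[c(1, 3)]),
                      motion_params(8, 0.005))
  expect_true(all(m1$motion_flag == 0L))
})

test_that("jittered timestamps exercise the resampler", {
  spec <- scene_spec(rows = 8, cols = 10, duration_s = 12,
                     cluster = list(rows = 3:6, cols = 4:8, rr_bpm = 45,
                                    amplitude = 0.3, harmonic = 0,
                                    edge_offset = 2),
                     timestamps = "jitter", seed = 4)
  rec <- generate_scene(spec)
  dt <- diff(rec$stacks[[1]]$timestamps)
  expect_gt(max(dt) / min(dt), 1.05)            # genuinely non-uniform
  expect_equal(mean(dt), 1 / 8.7, tolerance = 0.05)
  wins <- window_stack(rec$stacks[[1]])
  expect_gt(length(wins), 0)
  expect_true(all(vapply(wins, function(w) dim(w$frames)[1], integer(1))
                  == 72L))
})
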
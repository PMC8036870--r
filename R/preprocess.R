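#' Resample a frame stack to a uniform rate
#'
#' Each pixel's time series is linearly interpolated onto an arithmetic
#' grid at `target_rate` spanning the recorded time span. No
#' extrapolation is performed: the grid is clipped to
#' `[first, last]` input timestamp, so edge samples are never invented.
#'
#' @param stack a [frame_stack()], at least 2 frames.
#' @param target_rate target sampling rate in Hz (default 9).
#' @return A [frame_stack()] on the uniform grid.
#' @examples
#' fs <- frame_stack(array(c(0, 1), c(2, 1, 1)), c(0, 2 / 9))
#' resample_uniform(fs, 9)$frames[2, 1, 1]  # 0.5 at t = 1/9 s
#' @export
resample_uniform <- function(stack, target_rate = 9) {
  stopifnot(inherits(stack, "frame_stack"))
  if (n_frames(stack) < 2L)
    stop("resampling needs at least 2 frames")
  if (target_rate <= 0) stop("`target_rate` must be positive")
  ts <- stack$timestamps
  t0 <- ts[1L]
  t1 <- ts[length(ts)]
  # grid t0 + k/rate, clipped to the recorded span (with fp slack)
  n_out <- floor((t1 - t0) * target_rate + 1e-9) + 1L
  grid <- t0 + (seq_len(n_out) - 1L) / target_rate

  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = d[1L])      # frames x pixels
  # shared interpolation weights: grid time g falls in [ts[i], ts[i+1]]
  idx <- findInterval(grid, ts, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(ts) - 1L)
  w <- (grid - ts[idx]) / (ts[idx + 1L] - ts[idx])
  w <- pmin(pmax(w, 0), 1)
  out <- (1 - w) * flat[idx, , drop = FALSE] +
    w * flat[idx + 1L, , drop = FALSE]
  frame_stack(array(out, c(n_out, d[2L], d[3L])), grid, stack$view_id)
}

#' Convert RGB frames to grayscale luma
#'
#' Fixed ITU-R BT.601 weights (0.299, 0.587, 0.114), the classic luma
#' conversion used by standard grayscale routines.
#'
#' @param rgb_frames numeric array `frames x rows x cols x 3`.
#' @param timestamps per-frame seconds.
#' @param view_id camera identifier.
#' @param weights length-3 RGB weights; default BT.601.
#' @return A single-channel [frame_stack()].
#' @export
to_grayscale <- function(rgb_frames, timestamps, view_id = 1L,
                         weights = c(0.299, 0.587, 0.114)) {
  d <- dim(rgb_frames)
  if (length(d) != 4L || d[4L] != 3L)
    stop("`rgb_frames` must be frames x rows x cols x 3")
  stopifnot(length(weights) == 3L)
  gray <- weights[1L] * rgb_frames[, , , 1L, drop = FALSE] +
    weights[2L] * rgb_frames[, , , 2L, drop = FALSE] +
    weights[3L] * rgb_frames[, , , 3L, drop = FALSE]
  frame_stack(array(gray, d[1:3]), timestamps, view_id)
}

#' Spatially downscale by block averaging
#'
#' Each output pixel is the mean of its `factor x factor` input block
#' (area downsampling: deterministic and anti-aliasing). Rows and columns
#' must be divisible by `factor`; trailing rows/cols are cropped
#' otherwise, with a warning.
#'
#' @param stack a [frame_stack()].
#' @param factor positive integer downscale factor (3 maps 576x768 RGB
#'   frames to 192x256).
#' @return A [frame_stack()] with `rows/factor x cols/factor` frames.
#' @export
downscale <- function(stack, factor) {
  stopifnot(inherits(stack, "frame_stack"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  if (factor == 1L) return(stack)
  d <- dim(stack$frames)
  keep_r <- (d[2L] %/% factor) * factor
  keep_c <- (d[3L] %/% factor) * factor
  if (keep_r < 1L || keep_c < 1L) stop("frame smaller than one block")
  x <- stack$frames
  if (keep_r != d[2L] || keep_c != d[3L]) {
    warning("frame not divisible by factor; cropping to ",
            keep_r, "x", keep_c)
    x <- x[, seq_len(keep_r), seq_len(keep_c), drop = FALSE]
  }
  nr <- keep_r %/% factor
  nc <- keep_c %/% factor
  # frames x (factor, nr) x (factor, nc) -> mean over the two factor axes
  dim(x) <- c(d[1L], factor, nr, factor, nc)
  out <- colMeans(aperm(x, c(2L, 4L, 1L, 3L, 5L)),
                  dims = 2L)            # mean over the factor x factor block
  frame_stack(array(out, c(d[1L], nr, nc)), stack$timestamps, stack$view_id)
}

#' Merge synchronized views into one image plane
#'
#' Frames are concatenated along the row axis: three 60x80 thermal views
#' become one 180x80 plane; a single view passes through unchanged. The
#' inverse split recovers each input exactly.
#'
#' @param stacks list of [frame_stack()]s sharing frame shape and
#'   timestamps.
#' @return A [frame_stack()] (view_id of the first input).
#' @export
merge_views <- function(stacks) {
  if (inherits(stacks, "frame_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1L,
            all(vapply(stacks, inherits, TRUE, "frame_stack")))
  if (length(stacks) == 1L) return(stacks[[1L]])
  shapes <- vapply(stacks, frame_shape, integer(2L))
  if (any(shapes[1L, ] != shapes[1L, 1L]) || any(shapes[2L, ] != shapes[2L, 1L]))
    stop("all views must share one frame shape")
  ts <- stacks[[1L]]$timestamps
  for (s in stacks[-1L]) {
    if (n_frames(s) != length(ts) || max(abs(s$timestamps - ts)) > 1e-6)
      stop("views must be temporally aligned on the same uniform grid")
  }
  nt <- length(ts)
  nr <- shapes[1L, 1L]
  nc <- shapes[2L, 1L]
  merged <- array(0, c(nt, nr * length(stacks), nc))
  for (v in seq_along(stacks)) {
    merged[, (v - 1L) * nr + seq_len(nr), ] <- stacks[[v]]$frames
  }
  frame_stack(merged, ts, stacks[[1L]]$view_id)
}

#' Split a recording at acquisition gaps
#'
#' The thermal acquisition leaves gaps of up to 4 s between consecutive
#' 20-min files; interpolating across them would invent signal. Any
#' inter-frame interval larger than `max_gap_s` (default two nominal
#' sample periods) splits the stack, and windows are later generated per
#' segment, never bridging a split.
#'
#' @param stack a [frame_stack()].
#' @param target_rate nominal rate used for the default gap limit.
#' @param max_gap_s gap threshold in seconds; default `2 / target_rate`.
#' @return List of [frame_stack()] segments in temporal order.
#' @export
segment_stack <- function(stack, target_rate = 9, max_gap_s = 2 / target_rate) {
  stopifnot(inherits(stack, "frame_stack"))
  dt <- diff(stack$timestamps)
  cuts <- which(dt > max_gap_s)
  if (length(cuts) == 0L) return(list(stack))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n_frames(stack))
  lapply(seq_along(starts), function(i) {
    sel <- starts[i]:ends[i]
    frame_stack(stack$frames[sel, , , drop = FALSE],
                stack$timestamps[sel], stack$view_id)
  })
}

#' Slice a uniform stack into overlapping analysis windows
#'
#' Window `j` covers samples `[(j-1)*rate, (j-1)*rate + N)` with
#' `N = window_s * rate` (72 for 8 s at 9 Hz); consecutive windows
#' overlap by `window_s - slide_s` seconds. Recordings shorter than one
#' window yield an empty list, not an error. `index_origin_s` offsets the
#' global window index so windows of different gap segments keep distinct
#' indices.
#'
#' @param stack a uniformly sampled [frame_stack()].
#' @param window_s window length in seconds (default 8).
#' @param slide_s slide between consecutive windows in seconds (default 1).
#' @param index_origin_s recording time of global index 1 (default the
#'   stack's own first timestamp).
#' @return List of [window_view()]s.
#' @export
sliding_windows <- function(stack, window_s = 8, slide_s = 1,
                            index_origin_s = stack$timestamps[1L]) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is_uniform(stack))
    stop("`stack` must be uniformly sampled; run resample_uniform() first")
  rate <- frame_rate(stack)
  n <- as.integer(round(window_s * rate))
  step <- as.integer(round(slide_s * rate))
  if (step < 1L) stop("`slide_s` below one sample period")
  nt <- n_frames(stack)
  if (nt < n) return(list())
  starts <- seq.int(1L, nt - n + 1L, by = step)
  lapply(starts, function(s0) {
    t_start <- stack$timestamps[s0]
    window_view(stack$frames[s0 + 0:(n - 1L), , , drop = FALSE],
                start_s = t_start, rate_hz = rate,
                window_index =
                  as.integer(round((t_start - index_origin_s) / slide_s)) + 1L,
                view_id = stack$view_id)
  })
}

#' Segment, resample and window a raw recording in one call
#'
#' Convenience wrapper: splits at gaps, resamples each segment to
#' `rate_hz`, and windows each segment with a shared global index origin
#' (the recording's first timestamp), so STFT rows of gap-separated
#' windows keep their temporal position.
#'
#' @param stack raw [frame_stack()] (possibly non-uniform, with gaps).
#' @param rate_hz uniform target rate (default 9).
#' @param window_s,slide_s window geometry in seconds.
#' @return List of [window_view()]s across all segments.
#' @export
window_stack <- function(stack, rate_hz = 9, window_s = 8, slide_s = 1) {
  origin <- stack$timestamps[1L]
  segs <- segment_stack(stack, target_rate = rate_hz)
  out <- list()
  for (seg in segs) {
    if (n_frames(seg) < 2L) next
    uni <- resample_uniform(seg, rate_hz)
    out <- c(out, sliding_windows(uni, window_s, slide_s,
                                  index_origin_s = origin))
  }
  out
}
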
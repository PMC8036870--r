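#' Timestamped single-channel frame sequence
#'
#' A `frame_stack` holds one camera view as a 3-D intensity array
#' (frames x rows x cols) together with per-frame timestamps in seconds.
#' Timestamps may be non-uniform (the thermal setup free-runs at about
#' 8.7 Hz); [resample_uniform()] produces the uniform 9 Hz grid every
#' downstream stage assumes.
#'
#' @param frames numeric array, `frames x rows x cols`, finite.
#' @param timestamps numeric vector of seconds, strictly increasing, one
#'   per frame.
#' @param view_id integer camera identifier (1-based).
#' @return A `frame_stack` object.
#' @examples
#' fs <- frame_stack(array(0, c(5, 4, 6)), timestamps = (0:4) / 9)
#' dim(fs$frames)
#' @export
frame_stack <- function(frames, timestamps, view_id = 1L) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (frames x rows x cols)")
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames)))
    stop("frame intensities must be finite")
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != dim(frames)[1L])
    stop("one timestamp per frame is required (got ", length(timestamps),
         " timestamps for ", dim(frames)[1L], " frames)")
  if (length(timestamps) >= 2L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(
    list(frames = frames, timestamps = timestamps,
         view_id = as.integer(view_id)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  dur <- if (d[1L] > 1L) diff(range(x$timestamps)) else 0
  cat(sprintf("<frame_stack> view %d: %d frames of %dx%d, %.2f s\n",
              x$view_id, d[1L], d[2L], d[3L], dur))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[1L]
frame_shape <- function(stack) dim(stack$frames)[2:3]

#' Nominal (median) frame rate of a stack
#' @param stack a [frame_stack()].
#' @return Frames per second, or `NA` for a single frame.
#' @export
frame_rate <- function(stack) {
  if (n_frames(stack) < 2L) return(NA_real_)
  1 / stats::median(diff(stack$timestamps))
}

is_uniform <- function(stack, tol = 1e-6) {
  dt <- diff(stack$timestamps)
  length(dt) == 0L || diff(range(dt)) <= tol * mean(dt)
}

#' One analysis window of a uniformly sampled stack
#'
#' A `window_view` is the `N = window_s * rate` sample slice used by both
#' the motion detector and the rate estimator (8 s at 9 Hz, N = 72, slid
#' by 1 s).
#'
#' @param frames numeric array `N x rows x cols` at uniform rate.
#' @param start_s window start time in seconds (recording clock).
#' @param rate_hz sampling rate in Hz.
#' @param window_index 1-based global window index (`start_s / slide + 1`).
#' @param view_id camera identifier carried over from the source stack.
#' @return A `window_view` object.
#' @export
window_view <- function(frames, start_s, rate_hz, window_index = 1L,
                        view_id = 1L) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  structure(
    list(frames = frames, start_s = as.numeric(start_s),
         rate_hz = as.numeric(rate_hz),
         window_index = as.integer(window_index),
         view_id = as.integer(view_id)),
    class = "window_view")
}

#' @export
print.window_view <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<window_view> j=%d @ %.1f s: %d samples of %dx%d (%g Hz)\n",
              x$window_index, x$start_s, d[1L], d[2L], d[3L], x$rate_hz))
  invisible(x)
}

#' Intensity range of a window
#'
#' Max minus min over all pixels of all frames; the range-adaptive
#' denominator of the moving-pixel threshold `thr1 = Range(X) / f1` and of
#' the gradient threshold `Range(A) / kappa2`.
#'
#' @param window a [window_view()].
#' @return Non-negative scalar.
#' @export
window_range <- function(window) {
  r <- range(window$frames)
  r[2L] - r[1L]
}
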
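# run expr with a local, restored RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic infant-monitoring scene
#'
#' Describes the stated world the generator emulates: a thermal-like
#' 60x80 view with a spatially contiguous breathing cluster, sensor
#' noise at the 50 mK sensitivity of the cameras, and scheduled events
#' (gross type-1 motion, localized transient type-2 motion, a fast
#' soother-sucking oscillation, annotation-only exclusions).
#'
#' Defaults: baseline 30 (degC-like units), noise sd 0.05 (50 mK),
#' breathing amplitude 0.3 with a static +2 intensity step over the
#' cluster so its boundary is an edge, rate 40 BPM (a typical neonatal
#' rate), 9 Hz uniform sampling (or jittered ~8.7 Hz free-run).
#'
#' @param rows,cols frame shape (default 60 x 80, thermal).
#' @param duration_s recording length in seconds.
#' @param rate_hz nominal frame rate.
#' @param baseline background intensity.
#' @param bg_contrast amplitude of the static background structure (a
#'   smooth spatial ramp). Real thermal scenes have several degrees of
#'   static contrast between the infant and the surroundings, and the
#'   range-adaptive motion threshold `thr1 = Range(X)/f1` relies on
#'   scene contrast dominating breathing-sized changes; a structureless
#'   view would degenerate to thresholding noise against itself.
#' @param noise_sd i.i.d. Gaussian sensor noise sd per pixel-frame.
#' @param cluster list: `rows`, `cols` (index ranges), `rr_bpm`,
#'   `amplitude`, `harmonic` (first-harmonic fraction), `edge_offset`.
#' @param events NULL or data.frame with columns `type` (one of
#'   `type1`, `type2`, `nns`, `excluded`), `start_s`, `end_s` and,
#'   depending on type: `area_frac`, `jump` (type1); `row0`, `row1`,
#'   `col0`, `col1`, `amplitude` (type2/nns); `freq_hz` (nns).
#' @param timestamps `"uniform"` or `"jitter"` (free-running around
#'   `jitter_rate_hz` to exercise the resampler).
#' @param jitter_rate_hz mean free-run rate (default 8.7 Hz).
#' @param ref_rate_hz reference waveform sampling rate (default 62.5 Hz,
#'   chest-impedance-like).
#' @param ref_noise_sd noise sd on the reference waveform.
#' @param seed integer RNG seed; same seed, same recording, bit for bit.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(rows = 60L, cols = 80L, duration_s = 60,
                       rate_hz = 9, baseline = 30, bg_contrast = 4,
                       noise_sd = 0.05,
                       cluster = list(rows = 21:35, cols = 31:50,
                                      rr_bpm = 40, amplitude = 0.3,
                                      harmonic = 0, edge_offset = 2),
                       events = NULL,
                       timestamps = c("uniform", "jitter"),
                       jitter_rate_hz = 8.7,
                       ref_rate_hz = 62.5, ref_noise_sd = 0.05,
                       seed = 1L) {
  timestamps <- match.arg(timestamps)
  if (!is.null(cluster)) {
    stopifnot(max(cluster$rows) <= rows, max(cluster$cols) <= cols,
              min(cluster$rows) >= 1L, min(cluster$cols) >= 1L)
    if (is.null(cluster$harmonic)) cluster$harmonic <- 0
    if (is.null(cluster$edge_offset)) cluster$edge_offset <- 2
    f <- cluster$rr_bpm / 60
    if (f <= 0 || f >= rate_hz / 2)
      stop("cluster rate must lie below the Nyquist frequency")
  }
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("type", "start_s", "end_s") %in% names(events)),
              all(events$type %in% c("type1", "type2", "nns", "excluded")),
              all(events$end_s > events$start_s),
              all(events$start_s >= 0), all(events$end_s <= duration_s))
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 duration_s = duration_s, rate_hz = rate_hz,
                 baseline = baseline, bg_contrast = bg_contrast,
                 noise_sd = noise_sd,
                 cluster = cluster, events = events,
                 timestamps = timestamps, jitter_rate_hz = jitter_rate_hz,
                 ref_rate_hz = ref_rate_hz, ref_noise_sd = ref_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

event_field <- function(events, i, name, default) {
  if (name %in% names(events) && !is.na(events[[name]][i]))
    events[[name]][i]
  else default
}

# render one view's frames for given timestamps; noise drawn from the
# current RNG state
render_view <- function(spec, t, with_cluster = TRUE, view_events = NULL) {
  nf <- length(t)
  x <- array(spec$baseline + stats::rnorm(nf * spec$rows * spec$cols,
                                          sd = spec$noise_sd),
             c(nf, spec$rows, spec$cols))
  if (spec$bg_contrast > 0) {
    # static smooth scene structure: fixes Range(X) at a realistic
    # contrast without adding edges sharp enough for the gradient map
    ramp <- spec$bg_contrast *
      (outer(seq_len(spec$rows) / spec$rows,
             seq_len(spec$cols) / spec$cols, `+`) / 2)
    x <- x + rep(ramp, each = nf)
  }
  if (with_cluster && !is.null(spec$cluster)) {
    cl <- spec$cluster
    f <- cl$rr_bpm / 60
    osc <- cl$amplitude * (sin(2 * pi * f * t) +
                             cl$harmonic * sin(4 * pi * f * t))
    x[, cl$rows, cl$cols] <- x[, cl$rows, cl$cols] + cl$edge_offset + osc
  }
  ev <- view_events
  if (!is.null(ev) && nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      on <- t >= ev$start_s[i] & t < ev$end_s[i]
      if (!any(on)) next
      type <- ev$type[i]
      if (type == "type1") {
        frac <- event_field(ev, i, "area_frac", 0.02)
        jump <- event_field(ev, i, "jump", 5)
        npick <- ceiling(frac * spec$rows * spec$cols)
        pick <- sample.int(spec$rows * spec$cols, npick)
        flat <- matrix(x, nrow = nf)
        sgn <- (-1)^(seq_len(nf))[on]
        flat[on, pick] <- flat[on, pick] + jump * sgn
        x <- array(flat, dim(x))
      } else if (type %in% c("type2", "nns")) {
        r <- event_field(ev, i, "row0", 1L):event_field(ev, i, "row1", 6L)
        cc <- event_field(ev, i, "col0", 1L):event_field(ev, i, "col1", 6L)
        amp <- event_field(ev, i, "amplitude",
                           if (type == "nns") 0.3 else 2)
        if (type == "type2") {
          # smooth transient bump over the event duration
          phase <- (t[on] - ev$start_s[i]) / (ev$end_s[i] - ev$start_s[i])
          prof <- amp * 0.5 * (1 - cos(2 * pi * phase))
        } else {
          fq <- event_field(ev, i, "freq_hz", 2.5)
          prof <- amp * sin(2 * pi * fq * t[on])
        }
        x[on, r, cc] <- x[on, r, cc] + prof
      }
      # "excluded" events touch only the annotation track
    }
  }
  x
}

scene_timestamps <- function(spec) {
  if (spec$timestamps == "uniform") {
    seq(0, spec$duration_s - 1 / spec$rate_hz, by = 1 / spec$rate_hz)
  } else {
    dt <- 1 / spec$jitter_rate_hz
    incs <- dt + stats::runif(ceiling(spec$duration_s / dt) + 10L,
                              -0.25 * dt, 0.25 * dt)
    t <- cumsum(c(0, incs))
    t[t < spec$duration_s]
  }
}

annotate_frames <- function(spec, t) {
  ann <- data.frame(frame_index = seq_along(t), timestamp_s = t,
                    still = 1, type1 = 0, type2 = 0, nns = 0,
                    intervention = 0, other = 0)
  ev <- spec$events
  if (!is.null(ev) && nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      on <- t >= ev$start_s[i] & t < ev$end_s[i]
      col <- switch(ev$type[i], type1 = "type1", type2 = "type2",
                    nns = "nns", excluded = "other")
      ann[[col]][on] <- 1
      ann$still[on] <- 0
    }
  }
  ann
}

#' Generate a seeded synthetic recording
#'
#' Renders the scene frame by frame: Gaussian background noise around
#' the baseline, a breathing cluster oscillating at the set rate (with
#' optional first harmonic) carrying a static intensity step at its
#' boundary, scheduled type-1 / type-2 / sucking / exclusion events, a
#' frame-level annotation track consistent with the schedule, a
#' chest-impedance-like reference waveform at `ref_rate_hz`, and the
#' ground-truth rate per window. Identical seeds give bit-identical
#' recordings.
#'
#' @param spec a [scene_spec()].
#' @param window_s,slide_s window geometry used for the truth table.
#' @return A `synthetic_recording`: list with `stacks` (list of
#'   [frame_stack()]), `annotations`, `reference`, `truth`
#'   (window_index, start_s, rr_true_bpm, event_free), `schedule`,
#'   `spec`.
#' @export
generate_scene <- function(spec, window_s = 8, slide_s = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    t <- scene_timestamps(spec)
    x <- render_view(spec, t, with_cluster = TRUE, view_events = spec$events)
    stack <- frame_stack(x, t, view_id = 1L)
    ann <- annotate_frames(spec, t)
    tref <- seq(0, max(t), by = 1 / spec$ref_rate_hz)
    fr <- if (is.null(spec$cluster)) 0 else spec$cluster$rr_bpm / 60
    ref <- data.frame(
      timestamp_s = tref,
      value = sin(2 * pi * fr * tref) +
        stats::rnorm(length(tref), sd = spec$ref_noise_sd))
    truth <- window_truth(spec, t, window_s, slide_s)
    structure(list(stacks = list(stack), annotations = ann,
                   reference = ref, truth = truth,
                   schedule = spec$events, spec = spec),
              class = "synthetic_recording")
  })
}

window_truth <- function(spec, t, window_s = 8, slide_s = 1) {
  # start times of the windows the 9 Hz resampled grid will carry
  rate <- spec$rate_hz
  n_uniform <- floor((max(t) - t[1L]) * rate + 1e-9) + 1L
  nwin <- floor((n_uniform - window_s * rate) / (slide_s * rate)) + 1L
  starts <- if (nwin >= 1L) t[1L] + (seq_len(nwin) - 1L) * slide_s
  else numeric(0)
  if (length(starts) == 0L)
    return(data.frame(window_index = integer(0), start_s = numeric(0),
                      rr_true_bpm = numeric(0), event_free = logical(0)))
  ev <- spec$events
  event_free <- vapply(starts, function(s0) {
    is.null(ev) || nrow(ev) == 0L ||
      !any(ev$start_s < s0 + window_s & ev$end_s > s0)
  }, logical(1L))
  data.frame(window_index = as.integer(round(starts / slide_s)) + 1L,
             start_s = starts,
             rr_true_bpm = if (is.null(spec$cluster)) NA_real_
             else spec$cluster$rr_bpm,
             event_free = event_free)
}

#' Generate a synchronized multi-view recording
#'
#' All views share one timestamp grid and one event schedule; sensor
#' noise is independent per view. The breathing cluster appears in view
#' 1 (visible in at least one view, as in the three-camera thermal
#' setup); events carrying a `view` column are rendered only in that
#' view, others in all views.
#'
#' @param spec a [scene_spec()].
#' @param n_views number of camera views (default 3).
#' @param window_s,slide_s window geometry for the truth table.
#' @return A `synthetic_recording` whose `stacks` has `n_views` entries.
#' @export
make_multiview <- function(spec, n_views = 3L, window_s = 8, slide_s = 1) {
  stopifnot(inherits(spec, "scene_spec"), n_views >= 1L)
  if (n_views == 1L) return(generate_scene(spec, window_s, slide_s))
  with_seed(spec$seed, {
    t <- scene_timestamps(spec)
    ev <- spec$events
    stacks <- lapply(seq_len(n_views), function(v) {
      ev_v <- if (is.null(ev)) NULL
      else if ("view" %in% names(ev))
        ev[is.na(ev$view) | ev$view == v, , drop = FALSE]
      else ev
      frame_stack(render_view(spec, t, with_cluster = (v == 1L),
                              view_events = ev_v),
                  t, view_id = v)
    })
    ann <- annotate_frames(spec, t)
    tref <- seq(0, max(t), by = 1 / spec$ref_rate_hz)
    fr <- if (is.null(spec$cluster)) 0 else spec$cluster$rr_bpm / 60
    ref <- data.frame(
      timestamp_s = tref,
      value = sin(2 * pi * fr * tref) +
        stats::rnorm(length(tref), sd = spec$ref_noise_sd))
    truth <- window_truth(spec, t, window_s, slide_s)
    structure(list(stacks = stacks, annotations = ann, reference = ref,
                   truth = truth, schedule = ev, spec = spec),
              class = "synthetic_recording")
  })
}

#' Recover the event schedule from an annotation track
#'
#' Inverse of the frame annotation: contiguous runs of each event label
#' are turned back into (type, start, end) rows. Round-trips the
#' schedule of [generate_scene()] up to frame quantization.
#'
#' @param annotations annotation data.frame (see
#'   [ground_truth_windows()]).
#' @return data.frame `type`, `start_s`, `end_s` ordered by start.
#' @export
schedule_from_annotations <- function(annotations) {
  out <- list()
  t <- annotations$timestamp_s
  dt <- if (length(t) > 1L) stats::median(diff(t)) else 0
  for (col in c("type1", "type2", "nns", "other")) {
    if (!col %in% names(annotations)) next
    on <- as.numeric(annotations[[col]]) > 0
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        type = if (col == "other") "excluded" else col,
        start_s = t[starts[i]],
        end_s = t[ends[i]] + dt)
    }
  }
  if (length(out) == 0L)
    return(data.frame(type = character(0), start_s = numeric(0),
                      end_s = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start_s, res$type), , drop = FALSE]
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %d view(s), %d frames, %.1f s, %d event(s)\n",
    length(x$stacks), n_frames(x$stacks[[1L]]),
    max(x$stacks[[1L]]$timestamps),
    if (is.null(x$schedule)) 0L else nrow(x$schedule)))
  invisible(x)
}
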
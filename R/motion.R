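#' Gross-motion detector parameters
#'
#' `f1` divides the window's intensity range to give the moving-pixel
#' threshold `thr1 = Range(X) / f1`; `thr2` is the moving-pixel-ratio
#' threshold above which a window is declared type-1 motion. The
#' defaults (8, 0.005) are the values chosen by leave-one-subject-out
#' optimization on the clinical training set.
#'
#' @param f1 positive divisor of the window intensity range.
#' @param thr2 ratio threshold in `[0, 1]`.
#' @return A `motion_params` list.
#' @export
motion_params <- function(f1 = 8, thr2 = 0.005) {
  if (f1 <= 0) stop("`f1` must be positive")
  if (thr2 < 0 || thr2 > 1) stop("`thr2` must lie in [0, 1]")
  structure(list(f1 = f1, thr2 = thr2), class = "motion_params")
}

#' Moving-pixel maps and ratio of one window
#'
#' Per difference sample `u`, `D(u) = |X(u+1) - X(u)|` pixelwise; a
#' pixel is moving where `D > thr1` (strict), with
#' `thr1 = Range(X) / f1` computed per window and per view. The ratio
#' `s(u)` is the moving fraction of the frame. A constant window has
#' range 0, hence `thr1 = 0`, and any nonzero difference counts as
#' moving (degenerate but well-defined).
#'
#' @param window a [window_view()] with at least 2 samples.
#' @param params a [motion_params()] (only `f1` is used here).
#' @return List with `maps` (logical array `(N-1) x rows x cols`),
#'   `ratio` (numeric, length `N-1`, in `[0, 1]`), and `thr1`.
#' @export
moving_pixel_ratio <- function(window, params = motion_params()) {
  stopifnot(inherits(window, "window_view"))
  x <- window$frames
  nt <- dim(x)[1L]
  if (nt < 2L) stop("window must have at least 2 samples")
  thr1 <- window_range(window) / params$f1
  d <- abs(x[-1L, , , drop = FALSE] - x[-nt, , , drop = FALSE])
  mp <- d > thr1
  ratio <- rowMeans(matrix(mp, nrow = nt - 1L))
  list(maps = mp, ratio = ratio, thr1 = thr1)
}

# per-window maximum moving-pixel ratio for each candidate f1;
# classification at (f1, thr2) is then just max_ratio >= thr2
max_moving_ratio <- function(window, f1_values) {
  x <- window$frames
  nt <- dim(x)[1L]
  rng <- window_range(window)
  d <- abs(x[-1L, , , drop = FALSE] - x[-nt, , , drop = FALSE])
  d <- matrix(d, nrow = nt - 1L)
  vapply(f1_values, function(f1) {
    max(rowMeans(d > rng / f1))
  }, numeric(1L))
}

#' Classify one window as type-1 motion or usable
#'
#' Returns 1 (type-1 motion, unusable for rate estimation) iff any
#' difference sample of any view has moving-pixel ratio `s >= thr2`
#' (non-strict); the per-view decisions are OR-ed, mirroring the
#' three-camera thermal setup. Returns 0 (usable) otherwise.
#'
#' @param ratios a single result of [moving_pixel_ratio()] or a list of
#'   them (one per view, same window).
#' @param thr2 ratio threshold.
#' @return Integer 0 or 1.
#' @export
classify_window <- function(ratios, thr2) {
  if (!is.null(ratios$ratio)) ratios <- list(ratios)
  if (length(ratios) == 0L) stop("no moving-pixel series supplied")
  flagged <- any(vapply(ratios, function(r) any(r$ratio >= thr2), logical(1L)))
  as.integer(flagged)
}

#' Window ground truth from frame-level annotations
#'
#' A window is `excluded` if any of its frames carries an exclusion
#' label (interventions; someone in the background, baby out of bed,
#' camera motion, unsuitable view); exclusion takes priority. Otherwise
#' it is `type1_motion` if any frame has type-1 motion; otherwise
#' `usable` (type-2 motion, non-nutritive sucking and stillness are all
#' usable).
#'
#' @param annotations data.frame with columns `timestamp_s` and 0/1
#'   label columns among `type1`, `type2`, `nns`, `intervention`,
#'   `other` (labels are not exclusive).
#' @param windows list of [window_view()]s.
#' @param window_s window length in seconds.
#' @return data.frame with `window_index`, `start_s`,
#'   `label` (factor: excluded / type1_motion / usable).
#' @export
ground_truth_windows <- function(annotations, windows, window_s = 8) {
  stopifnot(is.data.frame(annotations), "timestamp_s" %in% names(annotations))
  getcol <- function(nm) {
    if (nm %in% names(annotations)) as.numeric(annotations[[nm]]) > 0
    else rep(FALSE, nrow(annotations))
  }
  excl <- getcol("intervention") | getcol("other")
  type1 <- getcol("type1")
  ts <- annotations$timestamp_s
  rows <- lapply(windows, function(w) {
    inwin <- ts >= w$start_s - 1e-9 & ts < w$start_s + window_s - 1e-9
    if (!any(inwin))
      stop("no annotated frames cover window at ", w$start_s, " s")
    lab <- if (any(excl[inwin])) "excluded"
    else if (any(type1[inwin])) "type1_motion"
    else "usable"
    data.frame(window_index = w$window_index, start_s = w$start_s,
               label = lab)
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label,
                      levels = c("excluded", "type1_motion", "usable"))
  out
}

# balanced accuracy with type-1 motion as positive class;
# if one class is absent, the defined rate stands alone (flagged upstream)
balanced_accuracy <- function(pred, truth_type1) {
  tp <- sum(pred == 1L & truth_type1)
  fn <- sum(pred == 0L & truth_type1)
  tn <- sum(pred == 0L & !truth_type1)
  fp <- sum(pred == 1L & !truth_type1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ba <- mean(c(sens, spec), na.rm = TRUE)
  list(balanced_accuracy = ba, sensitivity = sens, specificity = spec,
       tp = tp, fn = fn, tn = tn, fp = fp,
       one_class = is.na(sens) || is.na(spec))
}

# grid preference order: smallest thr2, then smallest f1 (most
# sensitive detector); used for both fold argmax ties and modal-set ties
pick_preferred <- function(cand) {
  cand[order(cand$thr2, cand$f1), , drop = FALSE][1L, , drop = FALSE]
}

#' Leave-one-subject-out optimization of (f1, thr2)
#'
#' For each held-out subject, every grid point is scored on the pooled
#' windows of the remaining subjects by balanced accuracy (type-1 motion
#' positive), excluded windows removed; the fold's candidate is the
#' argmax (ties: smallest thr2, then smallest f1). The returned set is
#' the modal candidate across folds, same tie rule. Between-subject
#' variability (bedding, temperature, viewpoint) motivates splitting by
#' subject rather than by time.
#'
#' @param subjects list; each subject is a list with `windows` (list of
#'   per-window view-lists of [window_view()]s, or of single
#'   [window_view()]s) and `labels` (character/factor per window:
#'   excluded / type1_motion / usable).
#' @param grid_f1 candidate `f1` values; default the 4..12 training grid.
#' @param grid_thr2 candidate `thr2` values; default the printed
#'   training grid (which contains 0.09 amid values near 0.01 — kept
#'   verbatim, likely a typo for 0.009; override via this argument).
#' @return A `cv_result` list: `chosen` (data.frame f1, thr2), `folds`
#'   (per-fold candidate + score), `scores` (fold x grid matrix of
#'   balanced accuracies), `grid` (data.frame of grid points).
#' @export
optimize_params <- function(subjects,
                            grid_f1 = 4:12,
                            grid_thr2 = c(0.004, 0.005, 0.006, 0.007, 0.008,
                                          0.09, 0.010, 0.011, 0.012)) {
  if (length(subjects) < 2L) stop("need at least 2 subjects for LOSO CV")
  grid <- expand.grid(f1 = grid_f1, thr2 = grid_thr2,
                      KEEP.OUT.ATTRS = FALSE)

  # precompute per subject: windows x f1 matrix of max moving ratios
  # (max over views: per-view OR at a threshold == threshold on the max)
  feats <- lapply(subjects, function(sub) {
    keep <- as.character(sub$labels) != "excluded"
    wins <- sub$windows[keep]
    mr <- t(vapply(wins, function(w) {
      views <- if (inherits(w, "window_view")) list(w) else w
      apply(vapply(views, max_moving_ratio, numeric(length(grid_f1)),
                   f1_values = grid_f1),
            1L, max)
    }, numeric(length(grid_f1))))
    list(max_ratio = mr,
         type1 = as.character(sub$labels)[keep] == "type1_motion")
  })

  nfold <- length(subjects)
  scores <- matrix(NA_real_, nfold, nrow(grid))
  fold_rows <- vector("list", nfold)
  for (k in seq_len(nfold)) {
    train <- feats[-k]
    mr <- do.call(rbind, lapply(train, `[[`, "max_ratio"))
    truth <- unlist(lapply(train, `[[`, "type1"))
    one_class <- length(unique(truth)) < 2L
    for (g in seq_len(nrow(grid))) {
      f1_idx <- match(grid$f1[g], grid_f1)
      pred <- as.integer(mr[, f1_idx] >= grid$thr2[g])
      scores[k, g] <- balanced_accuracy(pred, truth)$balanced_accuracy
    }
    best <- which(scores[k, ] == max(scores[k, ]))
    cand <- pick_preferred(grid[best, , drop = FALSE])
    fold_rows[[k]] <- data.frame(fold = k, f1 = cand$f1, thr2 = cand$thr2,
                                 balanced_accuracy = max(scores[k, ]),
                                 one_class_fold = one_class)
  }
  folds <- do.call(rbind, fold_rows)
  key <- paste(folds$f1, folds$thr2)
  tab <- table(key)
  modal <- names(tab)[tab == max(tab)]
  cand <- unique(folds[key %in% modal, c("f1", "thr2")])
  chosen <- pick_preferred(cand)
  structure(list(chosen = chosen, folds = folds, scores = scores,
                 grid = grid),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds; chosen f1 = %g, thr2 = %g\n",
              nrow(x$folds), x$chosen$f1, x$chosen$thr2))
  invisible(x)
}

#' Motion-classify every window of a multi-view recording
#'
#' @param window_sets list of per-window view-lists (or single
#'   [window_view()]s for one view).
#' @param params a [motion_params()].
#' @return data.frame with `window_index`, `start_s`, `motion_flag`
#'   (0/1) and `max_ratio` (max over views and samples).
#' @export
detect_motion <- function(window_sets, params = motion_params()) {
  rows <- lapply(window_sets, function(w) {
    views <- if (inherits(w, "window_view")) list(w) else w
    ratios <- lapply(views, moving_pixel_ratio, params = params)
    data.frame(window_index = views[[1L]]$window_index,
               start_s = views[[1L]]$start_s,
               motion_flag = classify_window(ratios, params$thr2),
               max_ratio = max(vapply(ratios, function(r) max(r$ratio),
                                      numeric(1L))))
  })
  do.call(rbind, rows)
}
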
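#' Agreement metrics between estimated and reference rates
#'
#' Pairwise comparison of per-window rates: mean absolute error, root
#' mean square error, percentage of correct estimation PR (fraction of
#' windows with `|error| <= tolerance`; the default 3.75 BPM is the
#' frequency quantum an 8 s window imposes, inclusive comparison),
#' Bland-Altman bias and 95% limits of agreement
#' (`bias +/- 1.96 * sd(est - ref)`, sample sd), and Pearson
#' correlation. Pairs with a missing value on either side are dropped.
#'
#' @param est,ref numeric vectors of rates in BPM, paired by window.
#' @param tolerance PR tolerance in BPM (default 3.75).
#' @return List: `n`, `mae_bpm`, `rmse_bpm`, `pr_pct`, `bias_bpm`,
#'   `loa_lower_bpm`, `loa_upper_bpm`, `pearson_r`.
#' @examples
#' rr_metrics(c(40, 42), c(41, 41))  # MAE = RMSE = 1, PR = 100
#' @export
rr_metrics <- function(est, ref, tolerance = 3.75) {
  if (length(est) != length(ref))
    stop("`est` and `ref` must be paired (equal length)")
  keep <- !is.na(est) & !is.na(ref)
  est <- est[keep]
  ref <- ref[keep]
  if (length(est) == 0L) stop("no complete pairs to compare")
  d <- est - ref
  bias <- mean(d)
  sdd <- if (length(d) > 1L) stats::sd(d) else 0
  r <- if (length(d) > 2L && stats::sd(est) > 0 && stats::sd(ref) > 0)
    stats::cor(est, ref) else NA_real_
  list(n = length(est),
       mae_bpm = mean(abs(d)),
       rmse_bpm = sqrt(mean(d^2)),
       pr_pct = 100 * mean(abs(d) <= tolerance),
       bias_bpm = bias,
       loa_lower_bpm = bias - 1.96 * sdd,
       loa_upper_bpm = bias + 1.96 * sdd,
       pearson_r = r)
}

#' Motion-classification metrics
#'
#' Confusion statistics with type-1 motion as the positive class (the
#' detector aims at the unusable moments): sensitivity, specificity,
#' accuracy, and balanced accuracy — the mean of sensitivity and
#' specificity, preferred because usable windows heavily outnumber
#' type-1 windows. Excluded windows must be removed beforehand. If a
#' class is absent its rate is NA and balanced accuracy falls back to
#' the defined rate.
#'
#' @param predicted 0/1 (or usable/type1_motion) predictions.
#' @param truth same encoding, ground truth.
#' @return List: `n`, `tp`, `fp`, `tn`, `fn`, `accuracy_pct`,
#'   `balanced_accuracy_pct`, `sensitivity_pct`, `specificity_pct`.
#' @export
classification_metrics <- function(predicted, truth) {
  as01 <- function(x) {
    if (is.numeric(x) || is.logical(x)) return(as.integer(x != 0))
    x <- as.character(x)
    bad <- setdiff(unique(x), c("type1_motion", "usable", "type1"))
    if (length(bad))
      stop("unexpected labels: ", paste(bad, collapse = ", "),
           " (remove excluded windows first)")
    as.integer(x %in% c("type1_motion", "type1"))
  }
  p <- as01(predicted)
  y <- as01(truth)
  if (length(p) != length(y)) stop("length mismatch")
  ba <- balanced_accuracy(p, y == 1L)
  list(n = length(p), tp = ba$tp, fp = ba$fp, tn = ba$tn, fn = ba$fn,
       accuracy_pct = 100 * mean(p == y),
       balanced_accuracy_pct = 100 * ba$balanced_accuracy,
       sensitivity_pct = 100 * ba$sensitivity,
       specificity_pct = 100 * ba$specificity)
}

#' Percentage of time used
#'
#' PT: share of included windows (exclusions already removed from the
#' mask) that the motion detector leaves usable, i.e. the fraction of
#' monitorable time the method actually monitors. Subset PTs (e.g. over
#' type-2-only windows) are obtained by passing the corresponding mask.
#'
#' @param motion_flags 0/1 per window (1 = type-1 motion).
#' @param included_mask logical per window, TRUE where the window counts
#'   (default all).
#' @return PT in percent.
#' @export
percentage_time_used <- function(motion_flags,
                                 included_mask = rep(TRUE,
                                                     length(motion_flags))) {
  stopifnot(length(motion_flags) == length(included_mask))
  n_inc <- sum(included_mask)
  if (n_inc == 0L) stop("no included windows")
  100 * sum(motion_flags == 0L & included_mask) / n_inc
}

#' Full metric report for an RR track
#'
#' Combines [rr_metrics()], [percentage_time_used()] and, when window
#' ground-truth labels are supplied, [classification_metrics()] into the
#' report the pipeline writes as JSON.
#'
#' @param track data.frame from [rr_track()] (columns `rr_video_bpm`,
#'   `motion_flag`).
#' @param reference data.frame from [reference_rr()], joined on
#'   `window_index` (optional).
#' @param truth_labels optional factor/character of window ground truth
#'   (excluded / type1_motion / usable), aligned with `track` rows.
#' @param tolerance PR tolerance in BPM.
#' @return Nested list: `rr` (NULL without a reference), `motion`
#'   (NULL without labels), `pt_pct`, `n_windows`.
#' @export
metric_report <- function(track, reference = NULL, truth_labels = NULL,
                          tolerance = 3.75) {
  included <- rep(TRUE, nrow(track))
  motion_part <- NULL
  if (!is.null(truth_labels)) {
    truth_labels <- as.character(truth_labels)
    stopifnot(length(truth_labels) == nrow(track))
    included <- truth_labels != "excluded"
    motion_part <- classification_metrics(
      track$motion_flag[included], truth_labels[included])
  }
  rr_part <- NULL
  if (!is.null(reference)) {
    m <- merge(track, reference, by = "window_index")
    m <- m[m$motion_flag == 0L, , drop = FALSE]
    if (nrow(m) > 0L)
      rr_part <- rr_metrics(m$rr_video_bpm, m$rr_ref_bpm, tolerance)
  }
  list(rr = rr_part, motion = motion_part,
       pt_pct = percentage_time_used(track$motion_flag, included),
       n_windows = nrow(track))
}
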
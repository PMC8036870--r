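#' Pseudo-periodicity of each pixel
#'
#' Height of the normalized spectral peak: `q = max|y'| / sqrt(sum|y'|^2)`
#' per pixel, computed on the differentially filtered spectrum over the
#' full half grid. Bounded by 1 (Cauchy-Schwarz); an all-zero spectrum
#' gives `q = 0` by convention. A periodic pixel concentrates its energy
#' in one bin and scores near 1; broadband noise scores low.
#'
#' @param mag_filt magnitude matrix `bins x n_pixels` from
#'   [pixel_spectra()] with `differential = TRUE`.
#' @return Numeric vector of `q` values in `[0, 1]`, one per pixel.
#' @export
pseudo_periodicity <- function(mag_filt) {
  if (is.null(dim(mag_filt))) mag_filt <- matrix(mag_filt, ncol = 1L)
  peak <- apply(mag_filt, 2L, max)
  energy <- sqrt(colSums(mag_filt^2))
  q <- ifelse(energy > 0, peak / energy, 0)
  unname(q)
}

# strict local maxima of each column restricted to the in-band bins,
# using full-grid neighbors; plateaus resolved to their lowest index
band_peak_indices <- function(mag, ctx) {
  m <- nrow(mag)
  interior <- 2:(m - 1L)
  up <- mag[interior, , drop = FALSE] > mag[interior - 1L, , drop = FALSE]
  down <- mag[interior, , drop = FALSE] > mag[interior + 1L, , drop = FALSE]
  peaks <- up & down
  # plateau rule: lowest index of an equal run that falls afterwards
  flat <- up & (mag[interior, , drop = FALSE] ==
                  mag[interior + 1L, , drop = FALSE])
  if (any(flat)) {
    for (p in which(colSums(flat) > 0)) {
      col <- mag[, p]
      for (i in which(flat[, p]) + 1L) {
        j <- i
        while (j < m && col[j + 1L] == col[i]) j <- j + 1L
        if (j < m && col[j + 1L] < col[i]) peaks[i - 1L, p] <- TRUE
      }
    }
  }
  inband <- ctx$band[interior]
  lapply(seq_len(ncol(mag)), function(p) which(peaks[, p] & inband) + 1L)
}

#' Dominant respiration frequency per pixel, harmonic-aware
#'
#' For each pixel, the local maxima of the filtered spectrum inside the
#' respiration band are listed ascending as `h`. The lowest peak `h(1)`
#' is taken as the rate if some higher peak `h(z)` behaves like its
#' first harmonic: it lies within `1/(N*Ts)` (0.125 Hz for 8 s windows)
#' of `2 h(1)`, the unfiltered spectrum is weaker there than at `h(1)`,
#' and the filtered spectrum is at least as strong (differentiation
#' boosts high frequencies, so a true harmonic can dominate `y'` while
#' the fundamental dominates `y`). Otherwise the global argmax of the
#' filtered spectrum is used. Any frequency at or above `lim2`
#' (non-nutritive sucking and other fast oscillations) is suppressed to
#' zero.
#'
#' @param mag_filt,mag_raw magnitude matrices `bins x n_pixels`
#'   (differential and plain spectra on the same grid).
#' @param ctx a [spectral_context()].
#' @return Numeric vector of per-pixel rates in Hz, 0 where suppressed.
#' @export
dominant_frequency <- function(mag_filt, mag_raw, ctx) {
  if (is.null(dim(mag_filt))) mag_filt <- matrix(mag_filt, ncol = 1L)
  if (is.null(dim(mag_raw))) mag_raw <- matrix(mag_raw, ncol = 1L)
  stopifnot(all(dim(mag_filt) == dim(mag_raw)))
  tol <- 1 / (ctx$n * ctx$ts)
  peaks <- band_peak_indices(mag_filt, ctx)
  global_arg <- max.col(t(mag_filt), ties.method = "first")
  npx <- ncol(mag_filt)
  rr <- numeric(npx)
  for (p in seq_len(npx)) {
    h <- peaks[[p]]
    picked <- NA_real_
    if (length(h) >= 2L) {
      h1 <- h[1L]
      hz <- h[-1L]
      harmonic <- abs(ctx$freqs[hz] - 2 * ctx$freqs[h1]) < tol &
        mag_raw[hz, p] < mag_raw[h1, p] &
        mag_filt[hz, p] >= mag_filt[h1, p]
      if (any(harmonic)) picked <- ctx$freqs[h1]
    }
    if (is.na(picked)) picked <- ctx$freqs[global_arg[p]]
    rr[p] <- if (picked < ctx$lim2) picked else 0
  }
  rr
}

#' Respiration-rate cluster score
#'
#' Nonlinear 3x3 neighborhood filter on the dominant-frequency map:
#' `w = (1/9) * sum exp(-kappa1 * |rr_c - rr_n| / rr_c)` over the
#' neighborhood. Pixels whose own rate is 0 (suppressed or DC-dominated,
#' e.g. type-2 motion regions) would divide by zero; their score is
#' forced to 0, so zero clusters never look coherent. Border pixels get
#' 0.
#'
#' @param rrhat numeric matrix of per-pixel rates in Hz (0 = suppressed).
#' @param kappa1 frequency-similarity sharpness (default 70).
#' @return Numeric matrix `W`, same shape, in `[0, 1]`.
#' @export
cluster_filter <- function(rrhat, kappa1 = 70) {
  stopifnot(is.matrix(rrhat))
  nr <- nrow(rrhat)
  nc <- ncol(rrhat)
  w <- matrix(0, nr, nc)
  if (nr < 3L || nc < 3L) return(w)
  ri <- 2:(nr - 1L)
  ci <- 2:(nc - 1L)
  centre <- rrhat[ri, ci, drop = FALSE]
  acc <- matrix(0, nr - 2L, nc - 2L)
  for (dr in -1:1) for (dc in -1:1) {
    nb <- rrhat[ri + dr, ci + dc, drop = FALSE]
    acc <- acc + exp(-kappa1 * abs(centre - nb) / centre)
  }
  acc <- acc / 9
  acc[!is.finite(acc) | centre == 0] <- 0
  w[ri, ci] <- acc
  w
}

#' Gradient (edge) feature of a window
#'
#' Respiration motion is visible only at intensity edges (blanket or
#' chest/neck contours). The frames of the window are averaged into one
#' image and a pixel is marked 1 where the spatial gradient magnitude
#' exceeds `Range(A)/kappa2`, making the threshold independent of the
#' modality's intensity scale. Central differences in the interior,
#' one-sided at borders. A constant window has range 0 and zero
#' gradient, so G is all zeros.
#'
#' @param window a [window_view()].
#' @param kappa2 range divisor for the edge threshold (default 16).
#' @return Binary (0/1) matrix `rows x cols`.
#' @export
gradient_feature <- function(window, kappa2 = 16) {
  stopifnot(inherits(window, "window_view"))
  d <- dim(window$frames)
  abar <- matrix(colMeans(matrix(window$frames, nrow = d[1L])), d[2L], d[3L])
  gm <- spatial_gradient(abar, along_rows = TRUE)
  gl <- spatial_gradient(abar, along_rows = FALSE)
  thr <- window_range(window) / kappa2
  (sqrt(gm^2 + gl^2) > thr) * 1
}

# MATLAB-gradient-style derivative: central differences inside,
# one-sided full differences at the two borders
spatial_gradient <- function(img, along_rows = TRUE) {
  if (!along_rows) return(t(spatial_gradient(t(img), TRUE)))
  n <- nrow(img)
  g <- img * 0
  if (n == 1L) return(g)
  g[1L, ] <- img[2L, ] - img[1L, ]
  g[n, ] <- img[n, ] - img[n - 1L, ]
  if (n > 2L)
    g[2:(n - 1L), ] <- (img[3:n, , drop = FALSE] -
                          img[1:(n - 2L), , drop = FALSE]) / 2
  g
}

# min-max normalization to [0, 1]; a constant map becomes all zeros
minmax_norm <- function(x) {
  r <- range(x)
  if (r[2L] <= r[1L]) return(x * 0)
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Fuse the three features and pick the core pixel
#'
#' Q, W and G are each min-max normalized to `[0, 1]` and multiplied
#' into V; any feature at zero vetoes the pixel. The core pixel is the
#' argmax of V (ties: lowest row, then lowest column). If V is
#' identically zero no pixel is trustworthy and the window is flagged
#' low-quality instead of emitting an arbitrary estimate.
#'
#' @param Q,W,G feature matrices of one shape (pseudo-periodicity,
#'   cluster score, edge map).
#' @return List: `V` (fused map), `core` (c(row, col) or NULL),
#'   `quality_ok` (logical).
#' @export
fuse_and_pick_core <- function(Q, W, G) {
  stopifnot(all(dim(Q) == dim(W)), all(dim(Q) == dim(G)))
  V <- minmax_norm(Q) * minmax_norm(W) * minmax_norm(G)
  if (max(V) <= 0)
    return(list(V = V, core = NULL, quality_ok = FALSE))
  flat <- which(V == max(V))
  # column-major which(): lowest column then row; reorder to lowest
  # (row, col) deterministically
  rc <- cbind(row = (flat - 1L) %% nrow(V) + 1L,
              col = (flat - 1L) %/% nrow(V) + 1L)
  rc <- rc[order(rc[, 1L], rc[, 2L]), , drop = FALSE]
  list(V = V, core = rc[1L, ], quality_ok = TRUE)
}
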
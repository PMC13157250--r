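# Per-ROI fluorescence traces and trace-level statistics: mean-over-mask
# extraction, donut-mask signal-to-background ratio, delta-F/F, zero-phase
# high-pass filtering, rolling-mean detrending (photobleaching correction)
# and rolling-mean smoothing. All operations are length-preserving and
# deterministic, and record their provenance in the trace object.

new_trace <- function(values, fps, roi_label = "", steps = character(0)) {
  check_that(all(is.finite(values)), "trace values must be finite")
  structure(list(values = as.numeric(values), fps = fps,
                 roi_label = roi_label, steps = steps),
            class = "gevi_trace")
}

append_step <- function(trace, step) {
  trace$steps <- c(trace$steps, step)
  trace
}

#' @export
print.gevi_trace <- function(x, ...) {
  cat(sprintf("gevi_trace '%s': %d samples @ %g fps, range [%.4g, %.4g]\n",
              x$roi_label, length(x$values), x$fps,
              min(x$values), max(x$values)))
  if (length(x$steps)) cat("  steps:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.gevi_trace <- function(x) length(x$values)

#' Extract the mean-fluorescence trace of an ROI
#'
#' `values[t]` is the mean of frame t over the mask pixels.
#'
#' @param movie a [gevi_movie()].
#' @param mask logical `H x W` matrix with at least one TRUE pixel, or an
#'   [roi_set()] plus `label`.
#' @param label ROI label when `mask` is an `roi_set`.
#' @return a `gevi_trace` (raw; provenance `"extract"`).
#' @export
extract_trace <- function(movie, mask, label = NULL) {
  check_that(inherits(movie, "gevi_movie"), "movie must be a gevi_movie")
  roi_label <- ""
  if (inherits(mask, "roi_set")) {
    check_that(!is.null(label) && label %in% names(mask$masks),
               "label '%s' not present in the ROI set", label)
    roi_label <- label
    mask <- mask$masks[[label]]
  }
  d <- dim(movie$frames)
  check_that(is.logical(mask) && all(dim(mask) == d[1:2]),
             "mask must be a logical H x W matrix matching the movie")
  check_that(any(mask), "mask is empty")
  px <- which(mask)
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  vals <- colMeans(flat[px, , drop = FALSE])
  new_trace(vals, movie$meta$fps, roi_label, steps = "extract")
}

# Annulus for cell i: pixels within scale * r_eq of the centroid, excluding
# the cell dilated by `gap` px and every other ROI's pixels.
donut_annulus <- function(masks, i, centroid, scale, gap) {
  m <- masks[[i]]
  h <- nrow(m); w <- ncol(m)
  r_eq <- sqrt(sum(m) / pi)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (rr - centroid[1])^2 + (cc - centroid[2])^2
  annulus <- d2 <= (scale * r_eq)^2
  # exclude the cell dilated by gap px (euclidean distance to any cell pixel)
  cell_px <- which(m, arr.ind = TRUE)
  if (gap > 0) {
    near <- matrix(FALSE, h, w)
    g <- ceiling(gap)
    for (dy in -g:g) for (dx in -g:g) {
      if (sqrt(dy^2 + dx^2) > gap + 1e-9) next
      ry <- cell_px[, 1] + dy; cx <- cell_px[, 2] + dx
      ok <- ry >= 1 & ry <= h & cx >= 1 & cx <= w
      near[cbind(ry[ok], cx[ok])] <- TRUE
    }
    annulus <- annulus & !near
  } else {
    annulus <- annulus & !m
  }
  for (j in seq_along(masks)) if (j != i) annulus <- annulus & !masks[[j]]
  annulus
}

#' Donut-shaped background mask around a cell
#'
#' The annulus contains pixels within `scale * r_eq` of the cell centroid
#' (default `scale = 2`: donut diameter twice the cell), excluding the cell
#' itself dilated by `gap` pixels and excluding every other ROI's pixels.
#' `r_eq = sqrt(area / pi)` is the cell's equivalent radius.
#'
#' @param roiset an [roi_set()].
#' @param label the cell's label.
#' @param scale outer radius as a multiple of `r_eq` (> 1).
#' @param gap guard gap between cell and annulus, in pixels.
#' @return logical `H x W` matrix; errors if the annulus is empty.
#' @export
donut_mask <- function(roiset, label, scale = 2.0, gap = 1) {
  check_that(inherits(roiset, "roi_set"), "roiset must be an roi_set")
  check_that(label %in% names(roiset$masks), "label '%s' not in ROI set", label)
  check_that(scale > 1, "scale must exceed 1")
  i <- match(label, names(roiset$masks))
  m <- roiset$masks[[i]]
  idx <- which(m, arr.ind = TRUE)
  centroid <- colMeans(idx)
  annulus <- donut_annulus(roiset$masks, i, centroid, scale, gap)
  check_that(any(annulus),
             "donut for '%s' is empty after exclusions", label)
  annulus
}

#' Signal-to-background ratio of a cell
#'
#' The time-and-pixel mean fluorescence over the cell mask divided by the
#' time-and-pixel mean over its donut background mask. Invariant to
#' multiplying the movie by a positive constant.
#'
#' @param movie a [gevi_movie()].
#' @param cell_mask,donut disjoint non-empty logical masks.
#' @return a single positive ratio.
#' @export
compute_sbr <- function(movie, cell_mask, donut) {
  check_that(any(cell_mask) && any(donut), "masks must be non-empty")
  check_that(!any(cell_mask & donut), "cell and donut masks must be disjoint")
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  cell_mean <- mean(flat[which(cell_mask), , drop = FALSE])
  bg_mean <- mean(flat[which(donut), , drop = FALSE])
  check_that(bg_mean > 0, "background mean is zero; SBR undefined")
  cell_mean / bg_mean
}

#' Zero-phase high-pass filter
#'
#' Second-order Butterworth high-pass applied forward and backward
#' (zero-phase, preserving spike timing). The trace mean is removed before
#' filtering and the signal is reflection-padded, so a constant trace maps
#' to zeros and edge transients are suppressed. Fast transients well above
#' the cutoff pass essentially unattenuated.
#'
#' @param trace a `gevi_trace`.
#' @param cutoff_hz cutoff frequency (default 1 Hz); must be below Nyquist.
#' @return filtered `gevi_trace` (provenance records the cutoff).
#' @export
highpass_filter <- function(trace, cutoff_hz = 1.0) {
  check_that(inherits(trace, "gevi_trace"), "trace must be a gevi_trace")
  fps <- trace$fps
  check_that(fps > 2 * cutoff_hz,
             "cutoff %g Hz is at or above Nyquist for %g fps", cutoff_hz, fps)
  v <- trace$values - mean(trace$values)
  n <- length(v)
  np <- min(n - 1L, as.integer(3 * ceiling(fps / cutoff_hz)))
  bw <- signal::butter(2, 2 * cutoff_hz / fps, type = "high")
  # mirror (even) reflection: robust to a noisy endpoint sample, which an
  # odd reflection would pivot on and leak into the passband near the edges
  vp <- c(rev(v[2:(np + 1L)]), v, rev(v[(n - np):(n - 1L)]))
  y <- signal::filtfilt(bw, vp)[(np + 1L):(np + n)]
  y <- y - mean(y)  # DC lies in the stopband; remove the padding residue
  out <- new_trace(y, fps, trace$roi_label, trace$steps)
  append_step(out, sprintf("highpass(%g Hz)", cutoff_hz))
}

#' Rolling-mean detrending (photobleaching correction)
#'
#' Divides the trace by its centered rolling mean and subtracts one,
#' yielding the dimensionless fractional deviation from the slow baseline.
#' Near the edges the series is extended by the linear trend of its
#' first/last window, so the rolling mean stays centered and unbiased
#' against a steep bleach trend. With `subtract = TRUE` the rolling mean is
#' subtracted instead (same units as the input).
#'
#' @param trace a `gevi_trace`.
#' @param window_s rolling-mean window in seconds (default 1.5 s); must
#'   cover at least 3 samples.
#' @param subtract subtract the rolling mean instead of dividing.
#' @return detrended `gevi_trace`.
#' @export
rolling_mean_detrend <- function(trace, window_s = 1.5, subtract = FALSE) {
  check_that(inherits(trace, "gevi_trace"), "trace must be a gevi_trace")
  w <- round(window_s * trace$fps)
  check_that(w >= 3, "window of %g s spans fewer than 3 samples", window_s)
  rm <- rolling_mean(trace$values, w, edges = "extrapolate")
  if (subtract) {
    y <- trace$values - rm
  } else {
    check_that(all(rm > 0), "rolling mean is non-positive; cannot divide")
    y <- trace$values / rm - 1
  }
  out <- new_trace(y, trace$fps, trace$roi_label, trace$steps)
  append_step(out, sprintf("detrend(%g s, %s)", window_s,
                           if (subtract) "subtract" else "divide"))
}

#' Rolling-mean smoothing
#'
#' Centered moving average over `window_s` seconds (default 30 ms). A window
#' of one frame is the identity.
#'
#' @param trace a `gevi_trace`.
#' @param window_s smoothing window in seconds.
#' @return smoothed `gevi_trace`.
#' @export
rolling_mean_smooth <- function(trace, window_s = 0.030) {
  check_that(inherits(trace, "gevi_trace"), "trace must be a gevi_trace")
  w <- max(1L, round(window_s * trace$fps))
  y <- rolling_mean(trace$values, w)
  out <- new_trace(y, trace$fps, trace$roi_label, trace$steps)
  append_step(out, sprintf("smooth(%g s)", window_s))
}

#' Fractional fluorescence change (delta-F/F)
#'
#' `(F(t) - Fbar) / Fbar` with `Fbar` the whole-recording mean of the trace;
#' the output has exactly zero mean and is invariant to multiplicative
#' rescaling of the input.
#'
#' @param trace a `gevi_trace` with positive mean.
#' @return delta-F/F `gevi_trace`.
#' @export
dff <- function(trace) {
  check_that(inherits(trace, "gevi_trace"), "trace must be a gevi_trace")
  fbar <- mean(trace$values)
  check_that(fbar > 0, "trace mean must be positive for delta-F/F")
  out <- new_trace(trace$values / fbar - 1, trace$fps, trace$roi_label,
                   trace$steps)
  append_step(out, "dff")
}

#' Write a trace to CSV with a provenance header
#'
#' Columns `frame` (0-based), `time_s`, `value`; processing steps are
#' recorded as leading `#` comment lines.
#'
#' @param trace a `gevi_trace`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# roi: %s", trace$roi_label), con)
  writeLines(sprintf("# fps: %g", trace$fps), con)
  writeLines(sprintf("# steps: %s", paste(trace$steps, collapse = " -> ")), con)
  df <- data.frame(frame = seq_along(trace$values) - 1L,
                   time_s = (seq_along(trace$values) - 1L) / trace$fps,
                   value = trace$values)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
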
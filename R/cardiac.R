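# Chamber-level cardiac analysis: processed chamber traces, beat detection
# with activation times (50% upstroke crossings), beat rate, APD50,
# atrial-to-ventricular delay, and the voltage-time footprint map (per-pixel
# temporal maximum delta-F/F within a fixed window).

#' Processed delta-F/F-style trace of a cardiac chamber
#'
#' Composition of [extract_trace()], [rolling_mean_detrend()] (1.5 s
#' photobleaching correction, yielding fractional deviation) and
#' [rolling_mean_smooth()] (30 ms), oriented so depolarization is positive.
#'
#' @param movie a [gevi_movie()].
#' @param roiset an [roi_set()] containing `label`.
#' @param label chamber label (e.g. `"atrium"`).
#' @param detrend_window_s,smooth_window_s rolling-mean windows (s).
#' @param polarity passed to [orient_trace()].
#' @return oriented, detrended, smoothed `gevi_trace`.
#' @export
chamber_trace <- function(movie, roiset, label, detrend_window_s = 1.5,
                          smooth_window_s = 0.030, polarity = "auto") {
  tr <- extract_trace(movie, roiset, label)
  tr <- rolling_mean_detrend(tr, detrend_window_s)
  tr <- rolling_mean_smooth(tr, smooth_window_s)
  orient_trace(tr, polarity)
}

#' Detect cardiac events on a processed chamber trace
#'
#' Beats are prominence peaks separated by at least one minimum beat period
#' (`1 / max_rate_hz`). Each beat's activation time is the linearly
#' interpolated crossing of 50% of its own peak on the rising flank; APD50
#' is the width at that level (rising to falling crossing). Beat rate is
#' `(n - 1) / (t_last - t_first)` for `n >= 2` events.
#'
#' @param trace oriented-positive `gevi_trace` (from [chamber_trace()]).
#' @param min_rate_hz,max_rate_hz plausible beat-rate bounds.
#' @param min_height_frac minimum peak height as a fraction of the largest
#'   excursion (rejects ripple between beats).
#' @return object of class `cardiac_events`: `activation_times_s` (strictly
#'   increasing), `peak_times_s`, `peak_dff`, `apd50_ms`, `rate_hz`,
#'   `fps`, `roi_label`.
#' @export
detect_cardiac_events <- function(trace, min_rate_hz = 0.3, max_rate_hz = 5,
                                  min_height_frac = 0.4) {
  check_that(inherits(trace, "gevi_trace"), "trace must be a gevi_trace")
  v <- trace$values
  fps <- trace$fps
  vmax <- max(v)
  check_that(vmax > 0, "no positive excursion; no beats found")
  min_sep <- max(1L, floor(fps / max_rate_hz * 0.8))
  peaks <- local_maxima(v, min_height = min_height_frac * vmax,
                        min_distance = min_sep)
  check_that(length(peaks) >= 1, "no beats found")

  act <- numeric(0); apd <- numeric(0); pk_t <- numeric(0); pk_v <- numeric(0)
  n <- length(v)
  for (p in peaks) {
    half <- 0.5 * v[p]
    # rising crossing: walk back from the peak to the last sample below half
    i <- p
    while (i > 1L && v[i - 1L] >= half) i <- i - 1L
    if (i == 1L) next  # upstroke truncated by the recording start
    frac_up <- (half - v[i - 1L]) / (v[i] - v[i - 1L])
    t_up <- (i - 2L + frac_up) / fps
    # falling crossing: walk forward to the first sample below half
    j <- p
    while (j < n && v[j + 1L] >= half) j <- j + 1L
    if (j == n) next  # repolarization truncated by the recording end
    frac_dn <- (v[j] - half) / (v[j] - v[j + 1L])
    t_dn <- (j - 1L + frac_dn) / fps
    act <- c(act, t_up)
    apd <- c(apd, (t_dn - t_up) * 1000)
    pk_t <- c(pk_t, (p - 1L) / fps)
    pk_v <- c(pk_v, v[p])
  }
  check_that(length(act) >= 1, "no complete beats found")
  rate <- if (length(act) >= 2) {
    (length(act) - 1) / (act[length(act)] - act[1])
  } else NA_real_
  if (!is.na(rate)) {
    check_that(rate >= min_rate_hz / 2 && rate <= max_rate_hz * 2,
               "measured rate %.3g Hz far outside the plausible [%g, %g] Hz",
               rate, min_rate_hz, max_rate_hz)
  }
  structure(list(activation_times_s = act, peak_times_s = pk_t,
                 peak_dff = pk_v, apd50_ms = apd, rate_hz = rate,
                 fps = fps, roi_label = trace$roi_label),
            class = "cardiac_events")
}

#' @export
print.cardiac_events <- function(x, ...) {
  cat(sprintf("cardiac_events '%s': %d beat(s), rate %.3g Hz, APD50 %.3g ms (median)\n",
              x$roi_label, length(x$activation_times_s), x$rate_hz,
              stats::median(x$apd50_ms)))
  invisible(x)
}

#' Atrial-to-ventricular conduction delay
#'
#' Each ventricular activation is matched to the nearest preceding atrial
#' activation within one beat period; the delay is the median of the matched
#' differences. Unmatched events on both sides are reported.
#'
#' @param atrial,ventricular `cardiac_events` for the two chambers.
#' @return object of class `av_delay`: `delay_s`, `delays_s` (per matched
#'   pair), `n_matched`, `n_unmatched_v`, `n_unmatched_a`.
#' @export
av_delay <- function(atrial, ventricular) {
  check_that(inherits(atrial, "cardiac_events") &&
               inherits(ventricular, "cardiac_events"),
             "inputs must be cardiac_events")
  a <- atrial$activation_times_s
  v <- ventricular$activation_times_s
  period <- if (!is.na(atrial$rate_hz) && atrial$rate_hz > 0) {
    1 / atrial$rate_hz
  } else Inf
  matched_a <- logical(length(a))
  delays <- numeric(0)
  for (tv in v) {
    prev <- which(a <= tv & tv - a < period)
    if (length(prev)) {
      k <- prev[which.max(a[prev])]
      delays <- c(delays, tv - a[k])
      matched_a[k] <- TRUE
    }
  }
  check_that(length(delays) >= 1, "no matchable atrial/ventricular pairs")
  structure(list(delay_s = stats::median(delays), delays_s = delays,
                 n_matched = length(delays),
                 n_unmatched_v = length(v) - length(delays),
                 n_unmatched_a = sum(!matched_a)),
            class = "av_delay")
}

#' @export
print.av_delay <- function(x, ...) {
  cat(sprintf("A-V delay: %.4g s (median of %d matched beats; %d V / %d A unmatched)\n",
              x$delay_s, x$n_matched, x$n_unmatched_v, x$n_unmatched_a))
  invisible(x)
}

#' Voltage-time footprint map
#'
#' For every pixel, the time series is detrended by its centered rolling
#' mean (photobleaching correction), oriented by `polarity`, referenced to
#' that pixel's baseline (mean of detrended out-of-window frames), and the
#' maximum delta-F/F within the analysis window is recorded along with the
#' frame of the maximum. Pixels whose rolling-mean baseline is non-positive
#' are flagged `NA`.
#'
#' @param movie a [gevi_movie()] (motion-corrected).
#' @param window_start_s window start (s); the window must lie inside the
#'   recording.
#' @param window_len_s window length (s, default 0.200).
#' @param detrend_window_s per-pixel rolling-mean window (s).
#' @param polarity `"positive"` or `"negative"`: optical polarity of
#'   depolarization; negative-going signals are negated before the maximum.
#' @return object of class `footprint_map`: `map` (`H x W` peak delta-F/F),
#'   `time_of_peak_s` (`H x W`), `window_start_s`, `window_len_s`.
#' @export
footprint_map <- function(movie, window_start_s, window_len_s = 0.200,
                          detrend_window_s = 1.5,
                          polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  check_that(inherits(movie, "gevi_movie"), "movie must be a gevi_movie")
  check_that(window_len_s > 0, "window_len_s must be positive")
  fps <- movie$meta$fps
  d <- dim(movie$frames)
  n_t <- d[3]
  f0 <- floor(window_start_s * fps) + 1L
  f1 <- min(n_t, ceiling((window_start_s + window_len_s) * fps))
  check_that(f0 >= 1 && f0 < f1 && f1 <= n_t,
             "analysis window [%g, %g] s lies outside the recording",
             window_start_s, window_start_s + window_len_s)
  flat <- matrix(movie$frames, d[1] * d[2], n_t)
  base <- rolling_mean_rows(flat, round(detrend_window_s * fps))
  bad <- apply(base <= 0, 1, any)
  base[base <= 0] <- NA
  dffm <- flat / base - 1
  if (polarity == "negative") dffm <- -dffm
  out_win <- setdiff(seq_len(n_t), f0:f1)
  pix_base <- rowMeans(dffm[, out_win, drop = FALSE])
  rel <- dffm[, f0:f1, drop = FALSE] - pix_base
  peak <- apply(rel, 1, max)
  tpk <- (f0 - 1L + apply(rel, 1, which.max) - 1L) / fps
  peak[bad] <- NA; tpk[bad] <- NA
  structure(list(map = matrix(peak, d[1], d[2]),
                 time_of_peak_s = matrix(tpk, d[1], d[2]),
                 window_start_s = window_start_s,
                 window_len_s = window_len_s),
            class = "footprint_map")
}

#' @export
print.footprint_map <- function(x, ...) {
  cat(sprintf("footprint_map: %d x %d, window [%.3f, %.3f] s, peak dF/F max %.4g\n",
              nrow(x$map), ncol(x$map), x$window_start_s,
              x$window_start_s + x$window_len_s, max(x$map, na.rm = TRUE)))
  invisible(x)
}

#' Plot a footprint map with a delta-F/F colorbar
#'
#' @param x a `footprint_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.footprint_map <- function(x, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::layout(matrix(1:2, 1), widths = c(5, 1))
  pal <- grDevices::hcl.colors(64, "Inferno")
  m <- x$map
  rng <- range(m, na.rm = TRUE)
  graphics::image(t(m[nrow(m):1, ]), col = pal, axes = FALSE,
                  main = "Voltage-time footprint (peak dF/F)", ...)
  graphics::par(mar = c(5, 1, 4, 3))
  ramp <- matrix(seq(rng[1], rng[2], length.out = 64), 1)
  graphics::image(ramp, col = pal, axes = FALSE)
  graphics::axis(4, at = c(0, 1), labels = sprintf("%.3f", rng))
  invisible(x)
}

#' Serialize cardiac results
#'
#' `write_cardiac_events()` writes a JSON summary; `write_footprint()`
#' writes the map as a float TIFF (with scale sidecar) and a rendered PNG
#' with a colorbar.
#'
#' @param events a `cardiac_events`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cardiac_events <- function(events, path) {
  jsonlite::write_json(unclass(events), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_cardiac_events
#' @param fp a `footprint_map`.
#' @param tiff_path,png_path output paths (PNG optional).
#' @export
write_footprint <- function(fp, tiff_path, png_path = NULL) {
  m <- fp$map
  m[!is.finite(m)] <- 0
  write_stack(list(m), tiff_path)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 480)
    plot(fp)
    grDevices::dev.off()
  }
  invisible(tiff_path)
}
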
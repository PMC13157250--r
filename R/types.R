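# Core data containers: acquisition metadata, movies, ROI sets, pipeline
# configuration. Frames are 0-based in time: frame k is at k / fps seconds.
# Pixel coordinates are (row, col), 0-based, origin top-left.

#' Acquisition metadata for a voltage-imaging recording
#'
#' @param fps frames per second (500 for neuronal recordings, 100 for
#'   cardiac recordings in the regimes this package targets).
#' @param duration_s recording length in seconds.
#' @param binning integer spatial binning factor; one of 1, 2, 4.
#' @param stage_label free-text developmental stage, e.g. `"25 hpf"`.
#' @return an object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(fps, duration_s, binning = 1L, stage_label = "") {
  check_that(is.numeric(fps) && length(fps) == 1 && fps > 0,
             "fps must be a single positive number")
  check_that(is.numeric(duration_s) && length(duration_s) == 1 && duration_s > 0,
             "duration_s must be a single positive number")
  check_that(binning %in% c(1L, 2L, 4L), "binning must be 1, 2 or 4")
  structure(list(fps = as.numeric(fps), duration_s = as.numeric(duration_s),
                 binning = as.integer(binning),
                 stage_label = as.character(stage_label)),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("Acquisition: %g fps, %g s, %dx%d binning%s\n",
              x$fps, x$duration_s, x$binning, x$binning,
              if (nzchar(x$stage_label)) paste0(", ", x$stage_label) else ""))
  invisible(x)
}

#' Construct a fluorescence movie
#'
#' A movie is a time-ordered stack of non-negative intensity frames stored as
#' an `H x W x T` array, plus acquisition metadata. The frame count must agree
#' with `round(fps * duration_s)` within one frame.
#'
#' @param frames numeric `H x W x T` array, all values >= 0, `T >= 2`.
#' @param meta an [acquisition_meta()].
#' @return an object of class `gevi_movie` with elements `frames` and `meta`.
#' @export
gevi_movie <- function(frames, meta) {
  check_that(is.array(frames) && length(dim(frames)) == 3,
             "frames must be an H x W x T array")
  check_that(dim(frames)[3] >= 2, "a movie needs at least 2 frames")
  check_that(all(is.finite(frames)) && min(frames) >= 0,
             "frame intensities must be finite and non-negative")
  check_that(inherits(meta, "acquisition_meta"), "meta must be acquisition_meta")
  expected <- round(meta$fps * meta$duration_s)
  check_that(abs(dim(frames)[3] - expected) <= 1,
             "frame count %d does not match fps x duration_s = %g (+/- 1)",
             dim(frames)[3], expected)
  structure(list(frames = frames, meta = meta), class = "gevi_movie")
}

#' @export
print.gevi_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("gevi_movie: %d frames of %d x %d @ %g fps (%.3g s), range [%.4g, %.4g]\n",
              d[3], d[1], d[2], x$meta$fps, x$meta$duration_s,
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.gevi_movie <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param movie a [gevi_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Construct an ROI set
#'
#' A named collection of boolean masks over the movie's pixel grid; every mask
#' must contain at least one pixel and labels must be unique.
#'
#' @param masks named list of logical `H x W` matrices.
#' @param kind `"neuron"` for cell ROIs or `"chamber"` for cardiac chambers.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(masks, kind = c("neuron", "chamber")) {
  kind <- match.arg(kind)
  check_that(is.list(masks) && length(masks) >= 1, "masks must be a non-empty list")
  labs <- names(masks)
  check_that(!is.null(labs) && all(nzchar(labs)) && !anyDuplicated(labs),
             "masks must have unique non-empty labels")
  dims <- unique(lapply(masks, dim))
  check_that(length(dims) == 1, "all masks must share the same H x W grid")
  for (lab in labs) {
    check_that(is.logical(masks[[lab]]) && any(masks[[lab]]),
               "mask '%s' must be logical with at least one TRUE pixel", lab)
  }
  structure(list(masks = masks, kind = kind), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  sizes <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("roi_set (%s): %d ROI(s) on %d x %d grid\n", x$kind,
              length(x$masks), nrow(x$masks[[1]]), ncol(x$masks[[1]])))
  for (lab in names(x$masks)) cat(sprintf("  %s: %d px\n", lab, sizes[[lab]]))
  invisible(x)
}

#' Pipeline configuration with field-validated defaults
#'
#' Collects every tunable of the analysis stages. Defaults are the values the
#' pipeline is designed around: 1 Hz high-pass cutoff, spike SNR threshold 3,
#' 10 ms synchrony bins, donut diameter twice the cell, 1.5 s detrending and
#' 30 ms smoothing windows for cardiac traces, and a 200 ms footprint window.
#'
#' @param highpass_cutoff_hz high-pass cutoff for neuronal traces (Hz).
#' @param snr_threshold per-spike SNR acceptance threshold.
#' @param refractory_ms minimum spike separation (ms).
#' @param candidate_sigma first-pass candidate threshold in units of the
#'   baseline noise sigma.
#' @param template_halfwidth_ms half-width of the spike-template window (ms).
#' @param bin_s synchrony firing-rate bin width (s).
#' @param donut_scale donut outer radius as a multiple of the cell's
#'   equivalent radius (2 = diameter twice the cell).
#' @param donut_gap_px guard gap between cell and donut (px).
#' @param detrend_window_s rolling-mean photobleaching-correction window (s).
#' @param smooth_window_s rolling-mean smoothing window (s).
#' @param footprint_window_s voltage-time footprint window length (s).
#' @param min_rate_hz,max_rate_hz plausible cardiac beat-rate bounds (Hz).
#' @param max_shift_px motion-correction search bound (px).
#' @param upsample subpixel refinement factor for shift estimation.
#' @param template_frames number of leading frames whose median forms the
#'   registration template.
#' @param polarity optical spike polarity: `"negative"`, `"positive"` or
#'   `"auto"`.
#' @param exclude_frames optional integer frames (0-based) to drop from
#'   cardiac analysis (manual artifact exclusion).
#' @param denoise apply the optional rolling-median spatial denoiser.
#' @param seed integer seed from which all pipeline randomness flows.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(highpass_cutoff_hz = 1.0,
                            snr_threshold = 3.0,
                            refractory_ms = 4,
                            candidate_sigma = 3.5,
                            template_halfwidth_ms = 8,
                            bin_s = 0.010,
                            donut_scale = 2.0,
                            donut_gap_px = 1L,
                            detrend_window_s = 1.5,
                            smooth_window_s = 0.030,
                            footprint_window_s = 0.200,
                            min_rate_hz = 0.3,
                            max_rate_hz = 5,
                            max_shift_px = 10,
                            upsample = 10L,
                            template_frames = 100L,
                            polarity = "negative",
                            exclude_frames = integer(0),
                            denoise = FALSE,
                            seed = 1L) {
  cfg <- list(highpass_cutoff_hz = highpass_cutoff_hz,
              snr_threshold = snr_threshold, refractory_ms = refractory_ms,
              candidate_sigma = candidate_sigma,
              template_halfwidth_ms = template_halfwidth_ms, bin_s = bin_s,
              donut_scale = donut_scale, donut_gap_px = donut_gap_px,
              detrend_window_s = detrend_window_s,
              smooth_window_s = smooth_window_s,
              footprint_window_s = footprint_window_s,
              min_rate_hz = min_rate_hz, max_rate_hz = max_rate_hz,
              max_shift_px = max_shift_px, upsample = as.integer(upsample),
              template_frames = as.integer(template_frames),
              polarity = polarity,
              exclude_frames = as.integer(exclude_frames),
              denoise = isTRUE(denoise), seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  pos <- c("highpass_cutoff_hz", "snr_threshold", "refractory_ms",
           "candidate_sigma", "template_halfwidth_ms", "bin_s",
           "detrend_window_s", "smooth_window_s", "footprint_window_s",
           "min_rate_hz", "max_rate_hz", "max_shift_px")
  for (f in pos) {
    check_that(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
               "config field '%s' must be a single positive number", f)
  }
  check_that(cfg$donut_scale > 1, "config field 'donut_scale' must exceed 1")
  check_that(cfg$donut_gap_px >= 0, "config field 'donut_gap_px' must be >= 0")
  check_that(cfg$upsample >= 1, "config field 'upsample' must be >= 1")
  check_that(cfg$template_frames >= 1,
             "config field 'template_frames' must be >= 1")
  check_that(cfg$max_rate_hz > cfg$min_rate_hz,
             "config field 'max_rate_hz' must exceed 'min_rate_hz'")
  check_that(cfg$polarity %in% c("negative", "positive", "auto"),
             "config field 'polarity' must be negative, positive or auto")
  check_that(all(cfg$exclude_frames >= 0),
             "config field 'exclude_frames' must be non-negative frame indices")
  invisible(TRUE)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (f in names(x)) {
    cat(sprintf("  %s: %s\n", f, paste(format(x[[f]]), collapse = " ")))
  }
  invisible(x)
}
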
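# Config-driven pipeline entry points tying the stages into the two
# analysis workflows (neuronal, cardiac) plus the simulators. Every run
# writes a manifest (config snapshot, inputs, outputs, seed, per-stage
# wall-clock) sufficient to re-run identically. A thin command-line wrapper
# over these functions lives at inst/exec/voltimg.R.

write_manifest <- function(out_dir, kind, cfg, inputs, outputs, seed, timings) {
  manifest <- list(pipeline = kind,
                   package_version = as.character(utils::packageVersion("voltimg")),
                   config = if (inherits(cfg, "pipeline_config")) unclass(cfg) else cfg,
                   inputs = inputs, outputs = outputs, seed = seed,
                   stage_seconds = timings)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

timed <- function(timings, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- expr
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(value = val, timings = timings)
}

#' Write simulator ground truth to JSON (plus activation-map TIFF)
#'
#' Spike times are stored in seconds; for cardiac truth the per-pixel
#' activation-offset map is written as a float TIFF side file next to the
#' JSON.
#'
#' @param truth the `truth` element of a simulator result.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  gt <- truth
  if (!is.null(gt$activation_offset_map)) {
    map_path <- sub("\\.json$", "_activation_map.tif", path)
    m <- gt$activation_offset_map
    m[!is.finite(m)] <- -1  # background marker
    write_stack(list(m), map_path)
    gt$activation_offset_map <- basename(map_path)
  }
  if (!is.null(gt$shifts)) gt$shifts <- unclass(gt$shifts)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run a simulator and write its fixture set
#'
#' Writes `movie.tif`, `rois.tif`, `ground_truth.json` (plus activation map
#' TIFF for cardiac runs) and `manifest.json`; re-running with the same
#' config and seed reproduces the files bit-identically.
#'
#' @param kind `"neuronal"` or `"cardiac"`.
#' @param cfg a [neuronal_sim_config()] or [cardiac_sim_config()]; its
#'   `seed` is overridden by `seed` when given.
#' @param out_dir output directory (created if missing).
#' @param seed optional integer seed override.
#' @return named list of written paths, invisibly.
#' @export
run_simulation <- function(kind = c("neuronal", "cardiac"), cfg, out_dir,
                           seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  st <- timed(timings, "simulate", {
    if (kind == "neuronal") simulate_neuronal_movie(cfg)
    else simulate_cardiac_movie(cfg)
  })
  sim <- st$value; timings <- st$timings
  paths <- list(movie = file.path(out_dir, "movie.tif"),
                rois = file.path(out_dir, "rois.tif"),
                ground_truth = file.path(out_dir, "ground_truth.json"))
  write_movie(sim$movie, paths$movie)
  write_roiset(sim$rois, paths$rois)
  write_ground_truth(sim$truth, paths$ground_truth)
  paths$manifest <- write_manifest(out_dir, paste0("simulate_", kind),
                                   unclass(cfg), list(), paths, cfg$seed,
                                   timings)
  invisible(paths)
}

#' Run the neuronal analysis pipeline
#'
#' Motion correction, per-cell trace extraction, 1 Hz high-pass,
#' orientation, matched-template spike detection at the configured SNR
#' threshold with the inverted-trace false-positive control, per-cell
#' donut SBR, and the synchrony matrix of detected spikes. All results plus
#' a manifest are written to `out_dir`.
#'
#' @param movie a [gevi_movie()] or a path to a movie TIFF.
#' @param rois an [roi_set()] or a path to an ROI label image.
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param meta an [acquisition_meta()], required when `movie` is a path.
#' @return list with `detections` (per cell), `sbr`, `synchrony`, `shifts`
#'   and the written `paths`, invisibly returned.
#' @export
run_neuronal <- function(movie, rois, cfg = pipeline_config(), out_dir,
                         meta = NULL) {
  if (is.character(movie)) {
    check_that(!is.null(meta), "meta is required when reading a movie path")
    movie <- read_movie(movie, meta)
  }
  if (is.character(rois)) rois <- read_roiset(rois, kind = "neuron")
  check_that(length(rois$masks) >= 1, "ROI set is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()

  st <- timed(timings, "motion_correction",
              motion_correct(movie, cfg$max_shift_px, cfg$upsample,
                             cfg$template_frames))
  mc <- st$value; timings <- st$timings
  if (cfg$denoise) {
    st <- timed(timings, "denoise", denoise_rolling_median(mc$movie))
    mc$movie <- st$value; timings <- st$timings
  }

  labels <- names(rois$masks)
  detections <- list(); sbr <- numeric(0); traces <- list()
  st <- timed(timings, "per_cell_analysis", {
    for (lab in labels) {
      raw <- extract_trace(mc$movie, rois, lab)
      hp <- highpass_filter(raw, cfg$highpass_cutoff_hz)
      ori <- orient_trace(hp, cfg$polarity)
      det <- detect_spikes_with_fp(ori, cfg$snr_threshold, cfg$refractory_ms,
                                   cfg$candidate_sigma,
                                   cfg$template_halfwidth_ms)
      detections[[lab]] <- det
      traces[[lab]] <- ori
      donut <- donut_mask(rois, lab, cfg$donut_scale, cfg$donut_gap_px)
      sbr[lab] <- compute_sbr(mc$movie, rois$masks[[lab]], donut)
    }
    NULL
  })
  timings <- st$timings

  spike_times <- lapply(detections, `[[`, "spike_times_s")
  sync <- if (length(labels) >= 2) {
    synchrony_matrix(spike_times, movie$meta$duration_s, cfg$bin_s)
  } else NULL

  paths <- list(shifts = file.path(out_dir, "shifts.csv"),
                sbr = file.path(out_dir, "sbr.json"))
  write_shifts(mc$shifts, paths$shifts)
  jsonlite::write_json(as.list(sbr), paths$sbr, auto_unbox = TRUE, digits = NA)
  for (lab in labels) {
    p <- file.path(out_dir, sprintf("detection_%s.json", lab))
    write_detection(detections[[lab]], p)
    paths[[paste0("detection_", lab)]] <- p
    pt <- file.path(out_dir, sprintf("trace_%s.csv", lab))
    write_trace(traces[[lab]], pt)
    paths[[paste0("trace_", lab)]] <- pt
  }
  if (!is.null(sync)) {
    paths$synchrony <- file.path(out_dir, "synchrony.csv")
    write_synchrony(sync, paths$synchrony)
  }
  paths$manifest <- write_manifest(out_dir, "neuronal", cfg,
                                   list(), paths, cfg$seed, timings)
  invisible(list(detections = detections, sbr = sbr, synchrony = sync,
                 shifts = mc$shifts, paths = paths))
}

#' Run the cardiac analysis pipeline
#'
#' Motion correction, chamber trace processing (1.5 s detrend + 30 ms
#' smoothing, delta-F/F scale), beat/APD50 detection per chamber, the
#' atrial-to-ventricular delay, and the voltage-time footprint map over a
#' 200 ms window starting 20 ms before the first detected atrial
#' activation. Results plus a manifest are written to `out_dir`.
#'
#' @inheritParams run_neuronal
#' @param rois must contain labels `"atrium"` and `"ventricle"`.
#' @return list with `events` (per chamber), `delay` ([av_delay()]),
#'   `footprint` and written `paths`, invisibly.
#' @export
run_cardiac <- function(movie, rois, cfg = pipeline_config(), out_dir,
                        meta = NULL) {
  if (is.character(movie)) {
    check_that(!is.null(meta), "meta is required when reading a movie path")
    movie <- read_movie(movie, meta)
  }
  if (is.character(rois)) rois <- read_roiset(rois, kind = "chamber")
  for (lab in c("atrium", "ventricle")) {
    check_that(lab %in% names(rois$masks),
               "chamber label '%s' missing from the ROI set", lab)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()

  st <- timed(timings, "motion_correction",
              motion_correct(movie, cfg$max_shift_px, cfg$upsample,
                             cfg$template_frames))
  mc <- st$value; timings <- st$timings
  mov <- mc$movie
  if (length(cfg$exclude_frames)) {
    keep <- setdiff(seq_len(n_frames(mov)), cfg$exclude_frames + 1L)
    mov <- gevi_movie(mov$frames[, , keep, drop = FALSE],
                      acquisition_meta(mov$meta$fps,
                                       length(keep) / mov$meta$fps,
                                       mov$meta$binning, mov$meta$stage_label))
  }

  st <- timed(timings, "events", {
    events <- list()
    for (lab in c("atrium", "ventricle")) {
      tr <- chamber_trace(mov, rois, lab, cfg$detrend_window_s,
                          cfg$smooth_window_s, cfg$polarity)
      events[[lab]] <- detect_cardiac_events(tr, cfg$min_rate_hz,
                                             cfg$max_rate_hz)
    }
    events
  })
  events <- st$value; timings <- st$timings
  delay <- av_delay(events$atrium, events$ventricle)

  win_start <- max(0, events$atrium$activation_times_s[1] - 0.020)
  fp_pol <- if (cfg$polarity == "auto") "negative" else cfg$polarity
  st <- timed(timings, "footprint",
              footprint_map(mov, win_start, cfg$footprint_window_s,
                            cfg$detrend_window_s, fp_pol))
  fp <- st$value; timings <- st$timings

  paths <- list(events_atrium = file.path(out_dir, "events_atrium.json"),
                events_ventricle = file.path(out_dir, "events_ventricle.json"),
                av_delay = file.path(out_dir, "av_delay.json"),
                footprint_tiff = file.path(out_dir, "footprint.tif"),
                footprint_png = file.path(out_dir, "footprint.png"),
                shifts = file.path(out_dir, "shifts.csv"))
  write_cardiac_events(events$atrium, paths$events_atrium)
  write_cardiac_events(events$ventricle, paths$events_ventricle)
  jsonlite::write_json(unclass(delay), paths$av_delay, auto_unbox = TRUE,
                       digits = NA)
  write_footprint(fp, paths$footprint_tiff, paths$footprint_png)
  write_shifts(mc$shifts, paths$shifts)
  paths$manifest <- write_manifest(out_dir, "cardiac", cfg, list(), paths,
                                   cfg$seed, timings)
  invisible(list(events = events, delay = delay, footprint = fp,
                 shifts = mc$shifts, paths = paths))
}

#' Optional rolling-median spatial denoiser
#'
#' A light 3 x 3 spatial median filter applied framewise; a simple
#' alternative noise-reduction step, off by default in the pipelines.
#'
#' @param movie a [gevi_movie()].
#' @return denoised [gevi_movie()].
#' @export
denoise_rolling_median <- function(movie) {
  d <- dim(movie$frames)
  out <- movie$frames
  for (t in seq_len(d[3])) {
    fr <- movie$frames[, , t]
    # 3x3 median via shifted stacks (border pixels keep their value)
    shifts <- expand.grid(dy = -1:1, dx = -1:1)
    stack <- vapply(seq_len(nrow(shifts)), function(k) {
      translate_bilinear(fr, shifts$dy[k], shifts$dx[k], fill = NA)
    }, matrix(0, d[1], d[2]))
    med <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
    out[, , t] <- med
  }
  gevi_movie(out, movie$meta)
}
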
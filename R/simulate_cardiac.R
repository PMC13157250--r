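# Synthetic two-chamber cardiac GEVI movies. The embryonic heart is modeled
# as two disjoint elliptical chambers (atrium and ventricle) on one grid;
# every beat starts at the atrial inflow edge, sweeps across the atrium at a
# fixed activation-time gradient, then enters the ventricle after the A-V
# conduction delay and sweeps across it. Atrial and ventricular pixels play
# stereotyped action-potential waveforms with chamber-specific durations
# (ventricular plateau longer than atrial).

#' Configuration for the cardiac movie simulator
#'
#' Defaults describe an arrested (non-contracting) embryonic zebrafish heart
#' imaged at 100 fps: beat rate 2 Hz, atrial-to-ventricular conduction delay
#' 100 ms, within-chamber activation spread 50 ms, APD 80 ms (atrium) and
#' 200 ms (ventricle), spike amplitude 5% of baseline, negative optical
#' polarity.
#'
#' @param height,width field size in pixels.
#' @param beat_rate_hz heart rate.
#' @param av_delay_s atrial-to-ventricular conduction delay (s).
#' @param activation_spread_s total activation-time spread across each
#'   chamber's long axis (s).
#' @param apd_a_ms,apd_v_ms atrial / ventricular action-potential durations
#'   (plateau end, ms); must satisfy `apd_v_ms > apd_a_ms > 0`.
#' @param upstroke_ms linear upstroke duration (ms).
#' @param repol_tau_ms exponential repolarization time constant (ms).
#' @param amplitude per-beat fractional fluorescence change.
#' @param polarity `"negative"` or `"positive"` optical polarity.
#' @param baseline tissue fluorescence; `background` elsewhere.
#' @param background non-tissue fluorescence level.
#' @param bleach_tau_s photobleaching time constant (`Inf` = none).
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sigma Gaussian noise sd.
#' @param fps frames per second.
#' @param duration_s recording length (s).
#' @param seed integer seed.
#' @param atrium,ventricle ellipse specs `list(cy, cx, ry, rx)` in pixels;
#'   defaults place them side by side with a gap.
#' @return an object of class `cardiac_sim_config`.
#' @export
cardiac_sim_config <- function(height = 80L, width = 96L,
                               beat_rate_hz = 2, av_delay_s = 0.10,
                               activation_spread_s = 0.05,
                               apd_a_ms = 80, apd_v_ms = 200,
                               upstroke_ms = 20, repol_tau_ms = 25,
                               amplitude = 0.05,
                               polarity = c("negative", "positive"),
                               baseline = 40, background = 10,
                               bleach_tau_s = Inf,
                               noise = c("none", "poisson", "gaussian"),
                               noise_sigma = 1,
                               fps = 100, duration_s = 10, seed = 1L,
                               atrium = NULL, ventricle = NULL) {
  polarity <- match.arg(polarity)
  noise <- match.arg(noise)
  check_that(apd_v_ms > apd_a_ms && apd_a_ms > 0,
             "need apd_v_ms > apd_a_ms > 0")
  check_that(av_delay_s >= 0, "av_delay_s must be >= 0")
  check_that(beat_rate_hz > 0 && duration_s > 0 && fps > 0,
             "rates and durations must be positive")
  check_that(activation_spread_s >= 0, "activation_spread_s must be >= 0")
  check_that(1 / beat_rate_hz >
               (apd_v_ms + upstroke_ms) / 1000 + av_delay_s / 2,
             "beat period too short for the configured ventricular APD")
  if (is.null(atrium)) {
    atrium <- list(cy = height / 2, cx = width * 0.27,
                   ry = height * 0.28, rx = width * 0.16)
  }
  if (is.null(ventricle)) {
    ventricle <- list(cy = height / 2, cx = width * 0.73,
                      ry = height * 0.30, rx = width * 0.18)
  }
  cfg <- structure(list(height = as.integer(height), width = as.integer(width),
                        beat_rate_hz = beat_rate_hz, av_delay_s = av_delay_s,
                        activation_spread_s = activation_spread_s,
                        apd_a_ms = apd_a_ms, apd_v_ms = apd_v_ms,
                        upstroke_ms = upstroke_ms, repol_tau_ms = repol_tau_ms,
                        amplitude = amplitude, polarity = polarity,
                        baseline = baseline, background = background,
                        bleach_tau_s = bleach_tau_s, noise = noise,
                        noise_sigma = noise_sigma, fps = fps,
                        duration_s = duration_s, seed = as.integer(seed),
                        atrium = atrium, ventricle = ventricle),
                   class = "cardiac_sim_config")
  masks <- chamber_masks(cfg)
  check_that(!any(masks$atrium & masks$ventricle),
             "atrium and ventricle ellipses overlap")
  cfg
}

chamber_masks <- function(cfg) {
  rr <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  cc <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  ell <- function(e) ((rr - e$cy) / e$ry)^2 + ((cc - e$cx) / e$rx)^2 <= 1
  list(atrium = ell(cfg$atrium), ventricle = ell(cfg$ventricle))
}

#' Stereotyped action-potential waveform
#'
#' Piecewise optical AP: linear upstroke from 0 to 1 over `upstroke_ms`, a
#' slight plateau decaying linearly to 90% of peak at `apd_ms`, then
#' exponential repolarization with time constant `repol_tau_ms`. Zero before
#' activation.
#'
#' @param t_rel time since activation (s), vectorized.
#' @param apd_ms plateau end (ms).
#' @param upstroke_ms upstroke duration (ms).
#' @param repol_tau_ms repolarization time constant (ms).
#' @return waveform values in `[0, 1]`.
#' @export
ap_waveform <- function(t_rel, apd_ms, upstroke_ms = 20, repol_tau_ms = 25) {
  up <- upstroke_ms / 1000; apd <- apd_ms / 1000; tau <- repol_tau_ms / 1000
  out <- numeric(length(t_rel))
  i1 <- t_rel >= 0 & t_rel < up
  out[i1] <- t_rel[i1] / up
  i2 <- t_rel >= up & t_rel < apd
  out[i2] <- 1 - 0.1 * (t_rel[i2] - up) / max(apd - up, 1e-9)
  i3 <- t_rel >= apd
  out[i3] <- 0.9 * exp(-(t_rel[i3] - apd) / tau)
  out
}

#' Simulate a two-chamber cardiac GEVI movie with ground truth
#'
#' Per-pixel activation time for beat b is
#' `t_b + (av_delay_s if ventricular) + gradient offset`, where the gradient
#' runs left-to-right along each chamber's long axis over
#' `activation_spread_s`. Each pixel's trace applies its chamber's AP
#' waveform at every activation, scaled by `amplitude` with the configured
#' polarity, then bleaching and noise.
#'
#' @param cfg a [cardiac_sim_config()].
#' @return list with `movie`, `rois` (labels `"atrium"`, `"ventricle"`) and
#'   `truth` (per-beat chamber activation times at the chamber entry edge,
#'   the per-pixel activation-offset map in seconds relative to the beat
#'   time, and the configured A-V delay).
#' @export
simulate_cardiac_movie <- function(cfg) {
  check_that(inherits(cfg, "cardiac_sim_config"), "cfg must be a cardiac_sim_config")
  n_t <- round(cfg$fps * cfg$duration_s)
  withr::with_seed(cfg$seed, {
    masks <- chamber_masks(cfg)
    h <- cfg$height; w <- cfg$width

    # per-pixel activation offset (s) relative to the beat start
    offset <- matrix(NA_real_, h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (ch in c("atrium", "ventricle")) {
      m <- masks[[ch]]
      x <- cc[m]
      frac <- if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else 0
      base <- if (ch == "ventricle") cfg$av_delay_s else 0
      offset[m] <- base + frac * cfg$activation_spread_s
    }

    period <- 1 / cfg$beat_rate_hz
    beat_times <- seq(0.2, cfg$duration_s - 1e-9, by = period)
    beat_times <- beat_times[beat_times < cfg$duration_s]

    tt <- (0:(n_t - 1L)) / cfg$fps
    pol <- if (cfg$polarity == "negative") -1 else 1

    # waveform lookup per chamber: activity(t) for a pixel with offset o is
    # sum over beats of ap_waveform(t - beat - o). Compute per distinct
    # offset value by quantizing offsets to the frame grid's resolution.
    q <- 1 / (cfg$fps * 4)  # quantize offsets to 1/4 frame
    off_q <- round(offset / q) * q
    apd <- c(atrium = cfg$apd_a_ms, ventricle = cfg$apd_v_ms)

    frames <- array(cfg$background, dim = c(h, w, n_t))
    plane <- h * w
    for (ch in c("atrium", "ventricle")) {
      m <- masks[[ch]]
      px <- which(m)
      for (o in sort(unique(off_q[px]))) {
        sel <- px[off_q[px] == o]
        s <- numeric(n_t)
        for (b in beat_times) {
          s <- s + ap_waveform(tt - b - o, apd[[ch]],
                               cfg$upstroke_ms, cfg$repol_tau_ms)
        }
        vals <- cfg$baseline * (1 + pol * cfg$amplitude * s)
        idx <- rep(sel, n_t) + rep((0:(n_t - 1L)) * plane, each = length(sel))
        frames[idx] <- rep(vals, each = length(sel))
      }
    }

    if (is.finite(cfg$bleach_tau_s)) {
      bl <- exp(-tt / cfg$bleach_tau_s)
      frames <- sweep(frames, 3, bl, `*`)
    }
    if (cfg$noise == "poisson") {
      frames[] <- stats::rpois(length(frames), frames)
    } else if (cfg$noise == "gaussian") {
      frames[] <- pmax(0, frames + stats::rnorm(length(frames), 0, cfg$noise_sigma))
    }

    meta <- acquisition_meta(cfg$fps, cfg$duration_s, stage_label = "synthetic")
    rois <- roi_set(masks, kind = "chamber")
    truth <- list(atrial_activation_times = beat_times,
                  ventricular_activation_times = beat_times + cfg$av_delay_s,
                  activation_offset_map = offset,
                  av_delay_s = cfg$av_delay_s,
                  beat_rate_hz = cfg$beat_rate_hz,
                  polarity = cfg$polarity)
    list(movie = gevi_movie(frames, meta), rois = rois, truth = truth)
  })
}
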
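# Synthetic neuronal GEVI movies with known ground truth. The generator
# emulates membrane-localized (ring-shaped) spiking cells over an
# autofluorescent background, with a fast biexponential spike kernel,
# shared-event synchrony between cells, single-exponential photobleaching,
# a rigid random-walk motion jitter and shot-like noise.

#' Configuration for the neuronal movie simulator
#'
#' Defaults describe the acquisition regime the analysis targets: 500 fps,
#' membrane rings of ~6 px radius on a 128 x 128 field, spike amplitude 5% of
#' baseline with negative optical polarity (fluorescence dips on
#' depolarization), a 1 ms rise / 5 ms decay kernel, and Poisson (shot)
#' noise.
#'
#' @param n_cells number of cells to place.
#' @param height,width field size in pixels.
#' @param cell_radius_px ring (membrane) radius in pixels.
#' @param ring_thickness_px ring thickness in pixels.
#' @param baseline mean cell-membrane fluorescence (arbitrary units).
#' @param background autofluorescent background level.
#' @param amplitude per-spike fractional fluorescence change `a` (>0).
#' @param polarity `"negative"` (dips) or `"positive"`.
#' @param tau_rise_ms,tau_decay_ms biexponential spike-kernel time constants.
#' @param rate_independent_hz per-cell independent Poisson spike rate.
#' @param rate_network_hz rate of shared network events.
#' @param participation probability a cell joins a given network event.
#' @param bleach_tau_s photobleaching time constant in seconds (`Inf` = none).
#' @param motion_sigma_px per-frame random-walk step of the rigid jitter.
#' @param psf_sigma_px Gaussian optics-blur sigma applied to the noiseless
#'   scene (0 = none; rings stay pixel-sharp and cell-mean trace identities
#'   are exact).
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sigma standard deviation for Gaussian noise.
#' @param fps frames per second.
#' @param duration_s recording length in seconds.
#' @param seed integer seed; identical config + seed gives identical movies.
#' @return an object of class `neuronal_sim_config`.
#' @export
neuronal_sim_config <- function(n_cells = 6L, height = 128L, width = 128L,
                                cell_radius_px = 6, ring_thickness_px = 2,
                                baseline = 40, background = 10,
                                amplitude = 0.05,
                                polarity = c("negative", "positive"),
                                tau_rise_ms = 1, tau_decay_ms = 5,
                                rate_independent_hz = 0.5,
                                rate_network_hz = 2,
                                participation = 0.8,
                                bleach_tau_s = Inf,
                                motion_sigma_px = 0,
                                psf_sigma_px = 0,
                                noise = c("poisson", "gaussian", "none"),
                                noise_sigma = 1,
                                fps = 500, duration_s = 10, seed = 1L) {
  polarity <- match.arg(polarity)
  noise <- match.arg(noise)
  check_that(n_cells >= 1, "n_cells must be >= 1")
  check_that(amplitude >= 0, "amplitude must be >= 0")
  check_that(participation >= 0 && participation <= 1,
             "participation must be in [0, 1]")
  check_that(rate_independent_hz >= 0 && rate_network_hz >= 0,
             "spike rates must be >= 0")
  check_that(tau_decay_ms > tau_rise_ms && tau_rise_ms > 0,
             "need tau_decay_ms > tau_rise_ms > 0")
  check_that(baseline > 0 && background >= 0,
             "baseline must be > 0 and background >= 0")
  check_that(bleach_tau_s > 0, "bleach_tau_s must be > 0 (Inf for none)")
  check_that(motion_sigma_px >= 0, "motion_sigma_px must be >= 0")
  check_that(psf_sigma_px >= 0, "psf_sigma_px must be >= 0")
  check_that(fps > 0 && duration_s > 0, "fps and duration_s must be > 0")
  structure(list(n_cells = as.integer(n_cells), height = as.integer(height),
                 width = as.integer(width), cell_radius_px = cell_radius_px,
                 ring_thickness_px = ring_thickness_px, baseline = baseline,
                 background = background, amplitude = amplitude,
                 polarity = polarity, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms,
                 rate_independent_hz = rate_independent_hz,
                 rate_network_hz = rate_network_hz,
                 participation = participation, bleach_tau_s = bleach_tau_s,
                 motion_sigma_px = motion_sigma_px,
                 psf_sigma_px = psf_sigma_px, noise = noise,
                 noise_sigma = noise_sigma, fps = fps,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "neuronal_sim_config")
}

#' Biexponential spike kernel with unit peak
#'
#' `kappa(t) = N * (exp(-t / tau_d) - exp(-t / tau_r))` for `t >= 0`, with
#' `N` chosen so the maximum is 1; the standard fast-indicator impulse shape.
#'
#' @param tau_rise_ms,tau_decay_ms time constants in milliseconds.
#' @param fps sampling rate used to evaluate the kernel.
#' @param length_ms kernel support; defaults to `8 * tau_decay_ms`.
#' @return numeric vector of kernel samples starting at t = 0.
#' @export
spike_kernel <- function(tau_rise_ms, tau_decay_ms, fps,
                         length_ms = 8 * tau_decay_ms) {
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  n <- max(2L, ceiling(length_ms / 1000 * fps))
  t <- (0:(n - 1L)) / fps
  # analytic peak time of the difference of exponentials
  tp <- log(td / tr) * tr * td / (td - tr)
  peak <- exp(-tp / td) - exp(-tp / tr)
  (exp(-t / td) - exp(-t / tr)) / peak
}

#' Generate per-cell spike trains with shared network events
#'
#' Each cell's train is the union of an independent homogeneous Poisson
#' process at `rate_independent_hz` and the subset of shared network events
#' (Poisson at `rate_network_hz`) the cell joins with probability
#' `participation`; shared events are simultaneous across participants.
#'
#' @param cfg a [neuronal_sim_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return a list of numeric spike-time vectors (seconds, sorted), one per
#'   cell, with the network event times in attribute `"network_events"`.
#' @export
generate_spike_trains <- function(cfg, seed = cfg$seed) {
  check_that(inherits(cfg, "neuronal_sim_config"), "cfg must be a neuronal_sim_config")
  withr::with_seed(seed, {
    n_net <- stats::rpois(1, cfg$rate_network_hz * cfg$duration_s)
    net_times <- sort(stats::runif(n_net, 0, cfg$duration_s))
    trains <- lapply(seq_len(cfg$n_cells), function(i) {
      n_ind <- stats::rpois(1, cfg$rate_independent_hz * cfg$duration_s)
      ind <- stats::runif(n_ind, 0, cfg$duration_s)
      joins <- stats::runif(n_net) < cfg$participation
      sort(c(ind, net_times[joins]))
    })
    names(trains) <- paste0("cell", seq_len(cfg$n_cells))
    attr(trains, "network_events") <- net_times
    trains
  })
}

# Place n disjoint ring masks; returns list(masks, full_masks, centers).
# full_masks are the filled disks (used for donut geometry and placement).
place_ring_cells <- function(cfg) {
  h <- cfg$height; w <- cfg$width
  r_out <- cfg$cell_radius_px
  r_in <- max(0, r_out - cfg$ring_thickness_px)
  margin <- ceiling(r_out) + 7L  # keep cells clear of motion-crop edges
  check_that(2 * margin < min(h, w),
             "field %dx%d too small for cells of radius %g", h, w, r_out)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  centers <- matrix(NA_real_, 0, 2)
  masks <- list(); disks <- list()
  occupied <- matrix(FALSE, h, w)
  tries <- 0L
  while (length(masks) < cfg$n_cells) {
    tries <- tries + 1L
    check_that(tries <= 2000L,
               "cannot place %d disjoint cells of radius %g in a %d x %d field",
               cfg$n_cells, r_out, h, w)
    cy <- stats::runif(1, margin, h - margin)
    cx <- stats::runif(1, margin, w - margin)
    d2 <- (rr - cy)^2 + (cc - cx)^2
    disk <- d2 <= (r_out + 2)^2  # small clearance between neighbours
    if (any(disk & occupied)) next
    ring <- d2 <= r_out^2 & d2 >= r_in^2
    if (!any(ring)) next
    occupied <- occupied | disk
    masks[[length(masks) + 1L]] <- ring
    disks[[length(disks) + 1L]] <- d2 <= r_out^2
    centers <- rbind(centers, c(cy, cx))
  }
  names(masks) <- paste0("cell", seq_along(masks))
  list(masks = masks, disks = disks, centers = centers)
}

#' Simulate a neuronal GEVI movie with ground truth
#'
#' Builds disjoint ring-shaped cells on a uniform background; each cell's
#' membrane intensity follows
#' `baseline * bleach(t) * (1 + polarity * a * sum_s kappa(t - t_s))` with the
#' unit-peak biexponential kernel. Frames are composited, rigidly shifted by
#' a reflected random walk (subpixel, bilinear, clipped to +/- 5 px), then
#' noise is applied.
#'
#' @param cfg a [neuronal_sim_config()].
#' @return a list with elements `movie` ([gevi_movie()]), `rois`
#'   ([roi_set()]) and `truth`, where `truth` holds per-cell spike times,
#'   the per-frame applied scene shifts (`dy`,`dx`; the correction shift is
#'   their negative), cell masks, realized per-cell SBR of the noiseless
#'   scene and per-spike peak delta-F/F.
#' @export
simulate_neuronal_movie <- function(cfg) {
  check_that(inherits(cfg, "neuronal_sim_config"), "cfg must be a neuronal_sim_config")
  n_t <- round(cfg$fps * cfg$duration_s)
  withr::with_seed(cfg$seed, {
    geom <- place_ring_cells(cfg)
    trains <- generate_spike_trains(cfg, seed = cfg$seed + 1L)

    # per-cell activity traces (unit baseline), spikes added at frame grid
    kern <- spike_kernel(cfg$tau_rise_ms, cfg$tau_decay_ms, cfg$fps)
    pol <- if (cfg$polarity == "negative") -1 else 1
    activity <- matrix(1, n_t, cfg$n_cells)
    for (i in seq_len(cfg$n_cells)) {
      s <- numeric(n_t)
      for (ts in trains[[i]]) {
        f0 <- floor(ts * cfg$fps) + 1L  # kernel onset at the spike frame
        idx <- f0:min(n_t, f0 + length(kern) - 1L)
        if (idx[1] <= n_t) s[idx] <- s[idx] + kern[seq_along(idx)]
      }
      activity[, i] <- 1 + pol * cfg$amplitude * s
    }

    bleach <- if (is.finite(cfg$bleach_tau_s)) {
      exp(-(0:(n_t - 1L)) / cfg$fps / cfg$bleach_tau_s)
    } else rep(1, n_t)

    # motion: reflected gaussian random walk, clipped to +/- 5 px
    shifts <- matrix(0, n_t, 2, dimnames = list(NULL, c("dy", "dx")))
    if (cfg$motion_sigma_px > 0) {
      for (ax in 1:2) {
        steps <- stats::rnorm(n_t, 0, cfg$motion_sigma_px)
        pos <- cumsum(steps)
        pos <- 5 - abs((pos + 5) %% 20 - 10)  # reflect into [-5, 5]
        shifts[, ax] <- pos
      }
    }

    # static scene plus per-cell increment images; the optics PSF (when
    # enabled) commutes with the rigid translation, so blurring the static
    # components once is exact
    static <- matrix(cfg$background, cfg$height, cfg$width)
    for (m in geom$masks) static[m] <- cfg$baseline
    incs <- lapply(geom$masks, function(m) cfg$baseline * (m * 1))
    if (cfg$psf_sigma_px > 0) {
      static <- gaussian_blur(static, cfg$psf_sigma_px)
      incs <- lapply(incs, gaussian_blur, sigma = cfg$psf_sigma_px)
    }
    # crop each increment image to its support for fast per-frame updates
    incs <- lapply(incs, function(im) {
      nz <- which(im > 1e-12, arr.ind = TRUE)
      rs <- range(nz[, 1]); cs <- range(nz[, 2])
      list(rows = rs[1]:rs[2], cols = cs[1]:cs[2],
           img = im[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE])
    })
    frames <- array(0, dim = c(cfg$height, cfg$width, n_t))
    for (t in seq_len(n_t)) {
      fr <- static
      for (i in seq_len(cfg$n_cells)) {
        d <- activity[t, i] - 1
        if (d != 0) {
          ic <- incs[[i]]
          fr[ic$rows, ic$cols] <- fr[ic$rows, ic$cols] + d * ic$img
        }
      }
      fr <- fr * bleach[t]
      if (shifts[t, 1] != 0 || shifts[t, 2] != 0) {
        fr <- translate_bilinear(fr, shifts[t, 1], shifts[t, 2],
                                 fill = cfg$background * bleach[t])
      }
      frames[, , t] <- fr
    }

    if (cfg$noise == "poisson") {
      frames[] <- stats::rpois(length(frames), frames)
    } else if (cfg$noise == "gaussian") {
      frames[] <- pmax(0, frames + stats::rnorm(length(frames), 0, cfg$noise_sigma))
    }

    meta <- acquisition_meta(cfg$fps, cfg$duration_s, stage_label = "synthetic")
    rois <- roi_set(geom$masks, kind = "neuron")

    # uniform background, so the noiseless scene's cell/donut ratio is exact
    true_sbr <- rep(cfg$baseline / cfg$background, cfg$n_cells)

    truth <- list(spike_times = trains,
                  network_events = attr(trains, "network_events"),
                  shifts = shifts,
                  centers = geom$centers,
                  true_sbr = true_sbr,
                  spike_peak_dff = pol * cfg$amplitude,
                  polarity = cfg$polarity)
    list(movie = gevi_movie(frames, meta), rois = rois, truth = truth)
  })
}
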
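# Synthetic-data generators: spike-train statistics, kernel shape, movie
# composition, determinism and conservation.

test_that("spike kernel has unit peak and biexponential shape", {
  k <- spike_kernel(1, 5, 500)
  expect_equal(max(k), 1, tolerance = 1e-4)  # sampled grid vs analytic peak
  expect_equal(k[1], 0)
  # analytic peak time ~2.01 ms -> frame 2 at 500 fps
  expect_equal(which.max(k), 2)
  expect_true(all(diff(k[which.max(k):length(k)]) <= 0))
})

test_that("spike trains: silent, fully shared, and Poisson-mean cases", {
  base <- neuronal_sim_config(n_cells = 3, rate_independent_hz = 0,
                              rate_network_hz = 0, duration_s = 10, seed = 1)
  expect_true(all(lengths(generate_spike_trains(base)) == 0))

  shared <- neuronal_sim_config(n_cells = 3, rate_independent_hz = 0,
                                rate_network_hz = 2, participation = 1,
                                duration_s = 10, seed = 2)
  tr <- generate_spike_trains(shared)
  expect_identical(tr[[1]], tr[[2]])
  expect_identical(tr[[2]], tr[[3]])
  expect_identical(sort(tr[[1]]), sort(attr(tr, "network_events")))

  # expected count 20 per cell; allow 3 * sqrt(20) over pooled seeds
  counts <- vapply(1:12, function(s) {
    length(generate_spike_trains(shared, seed = s)[[1]])
  }, numeric(1))
  expect_true(all(abs(counts - 20) <= 3 * sqrt(20)))
  expect_lt(abs(mean(counts) - 20), sqrt(20))
})

test_that("quiescent noiseless movie is constant; conservation holds", {
  cfg <- neuronal_sim_config(n_cells = 2, height = 48, width = 48,
                             amplitude = 0, motion_sigma_px = 0,
                             noise = "none", bleach_tau_s = Inf,
                             duration_s = 0.2, seed = 3)
  sim <- simulate_neuronal_movie(cfg)
  f1 <- sim$movie$frames[, , 1]
  for (t in 2:n_frames(sim$movie)) {
    expect_identical(sim$movie$frames[, , t], f1)
  }
  totals <- apply(sim$movie$frames, 3, sum)
  expect_equal(max(totals) - min(totals), 0)
})

test_that("a single noiseless spike dips the cell-mean trace by a x baseline", {
  cfg <- neuronal_sim_config(n_cells = 1, height = 48, width = 48,
                             rate_independent_hz = 0, rate_network_hz = 0,
                             noise = "none", duration_s = 1, seed = 4)
  sim <- simulate_neuronal_movie(cfg)
  # inject one spike by hand through the generator's own kernel arithmetic
  tr0 <- kernel_trace(0.5, duration_s = 1, amplitude = 0.05 * 40,
                      baseline = 40)
  expect_equal(min(tr0$values), 40 * (1 - 0.05), tolerance = 1e-6)
  # the simulated movie's own trace obeys the same identity
  cfg$rate_independent_hz <- 1
  sim <- simulate_neuronal_movie(cfg)
  ts <- sim$truth$spike_times$cell1
  if (length(ts) > 0) {
    tr <- extract_trace(sim$movie, sim$rois, "cell1")
    peak <- kernel_peak_frame(ts[1]) + 1L
    expect_equal(tr$values[peak], 40 * (1 - 0.05), tolerance = 0.01 * 40 * 0.05)
  }
})

test_that("cell-mean trace deviates by a x baseline at every true spike peak", {
  cfg <- neuronal_sim_config(n_cells = 3, height = 64, width = 64,
                             rate_independent_hz = 1, rate_network_hz = 1,
                             noise = "none", duration_s = 5, seed = 7)
  sim <- simulate_neuronal_movie(cfg)
  tr <- extract_trace(sim$movie, sim$rois, "cell2")
  ts <- sim$truth$spike_times$cell2
  # only isolated spikes have the clean single-kernel peak value
  isolated <- ts[vapply(ts, function(t0)
    all(abs(setdiff(ts, t0) - t0) > 0.06), logical(1))]
  isolated <- isolated[isolated < 4.9]
  skip_if(length(isolated) == 0)
  for (t0 in isolated) {
    peak <- kernel_peak_frame(t0) + 1L
    dev <- min(tr$values[peak + (-1:1)]) - 40
    expect_equal(dev, -0.05 * 40, tolerance = 0.01 * 40 * 0.05 + 1e-9)
  }
})

test_that("simulation is bit-identical for identical config and seed", {
  cfg <- neuronal_sim_config(n_cells = 2, height = 48, width = 48,
                             motion_sigma_px = 0.3, noise = "poisson",
                             duration_s = 0.3, seed = 11)
  a <- simulate_neuronal_movie(cfg)
  b <- simulate_neuronal_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  expect_identical(a$truth$shifts, b$truth$shifts)
})

test_that("shared events create positive binned-rate correlation, none when off", {
  on <- neuronal_sim_config(n_cells = 4, rate_independent_hz = 0.5,
                            rate_network_hz = 2, participation = 0.8,
                            duration_s = 60, seed = 12)
  m_on <- synchrony_matrix(generate_spike_trains(on), 60)
  expect_gt(mean(m_on[upper.tri(m_on)], na.rm = TRUE), 0.2)

  off <- neuronal_sim_config(n_cells = 4, rate_independent_hz = 3,
                             rate_network_hz = 0, duration_s = 60, seed = 13)
  m_off <- synchrony_matrix(generate_spike_trains(off), 60)
  expect_lt(abs(mean(m_off[upper.tri(m_off)], na.rm = TRUE)), 0.05)
})

test_that("cardiac ground truth: beat counts and exact A-V lag by construction", {
  cfg <- cardiac_sim_config(beat_rate_hz = 1, duration_s = 3, seed = 14)
  sim <- simulate_cardiac_movie(cfg)
  expect_length(sim$truth$atrial_activation_times, 3)
  expect_equal(sim$truth$ventricular_activation_times -
                 sim$truth$atrial_activation_times,
               rep(0.10, 3))
})

test_that("noiseless V chamber-mean trace lags A by the conduction delay", {
  cfg <- cardiac_sim_config(beat_rate_hz = 2, av_delay_s = 0.1,
                            duration_s = 5, seed = 15)
  sim <- simulate_cardiac_movie(cfg)
  half_cross <- function(lab) {
    v <- -(extract_trace(sim$movie, sim$rois, lab)$values - 40) # dips upward
    p <- which.max(v[1:60])
    half <- v[p] / 2
    i <- p; while (i > 1 && v[i - 1] >= half) i <- i - 1
    i
  }
  lag_frames <- half_cross("ventricle") - half_cross("atrium")
  expect_lte(abs(lag_frames - 0.1 * 100), 1)
})

test_that("invalid simulator configs fail with field-named errors", {
  expect_error(neuronal_sim_config(participation = 1.5), "participation")
  expect_error(neuronal_sim_config(tau_rise_ms = 5, tau_decay_ms = 2),
               "tau_decay_ms")
  expect_error(cardiac_sim_config(apd_a_ms = 300, apd_v_ms = 200), "apd_v_ms")
  expect_error(
    cardiac_sim_config(atrium = list(cy = 40, cx = 40, ry = 20, rx = 20),
                       ventricle = list(cy = 40, cx = 50, ry = 20, rx = 20)),
    "overlap")
  # too many cells for the field
  expect_error(simulate_neuronal_movie(
    neuronal_sim_config(n_cells = 60, height = 48, width = 48, seed = 1)),
    "cannot place")
})
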
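# Spike detection: orientation, noise estimation, matched-template
# detection with the SNR rule, inverted-trace false positives.

test_that("orientation: auto flips negative-going spikes, involution holds", {
  tr <- kernel_trace(c(1, 2, 3), duration_s = 5, amplitude = 2,
                     noise_sd = 0.2, polarity = -1)
  hp <- highpass_filter(tr, 1)
  ori <- orient_trace(hp, "auto")
  expect_true(attr(ori, "flipped"))
  expect_gt(max(ori$values), abs(min(ori$values)))
  # flipping a positive trace back equals the original
  pos <- kernel_trace(c(1, 2, 3), duration_s = 5, amplitude = 2,
                      noise_sd = 0.2, polarity = 1)
  hpp <- highpass_filter(pos, 1)
  ori2 <- orient_trace(hpp, "auto")
  expect_false(attr(ori2, "flipped"))
  expect_equal(ori2$values, hpp$values)
  expect_equal(orient_trace(hpp, "negative")$values, -hpp$values)
})

test_that("noise estimate: MAD consistency, zero for constants, spike robustness", {
  withr::with_seed(41, {
    v <- stats::rnorm(50000)
  })
  tr <- voltimg:::new_trace(v, 500, "n")
  expect_equal(estimate_noise(tr), 1.0, tolerance = 0.02)
  expect_equal(estimate_noise(voltimg:::new_trace(rep(3, 200), 500, "c")), 0)
  # sparse large spikes inflate sigma by < 5%
  spiky <- kernel_trace(seq(0.5, 95, by = 2), duration_s = 100,
                        amplitude = 8, noise_sd = 1, polarity = 1, seed = 42,
                        baseline = 0)
  clean <- voltimg:::new_trace(
    withr::with_seed(42, stats::rnorm(50000)), 500, "c")
  expect_lt(abs(estimate_noise(spiky) - estimate_noise(clean)) /
              estimate_noise(clean), 0.05)
})

test_that("flat traces yield zero spikes; detection is deterministic", {
  flat <- voltimg:::new_trace(rep(0, 1000), 500, "f")
  expect_length(detect_spikes(flat)$spike_frames, 0)
  tr <- kernel_trace(seq(1, 9, by = 0.7), amplitude = 2, noise_sd = 0.3,
                     polarity = 1, seed = 43, baseline = 0)
  a <- detect_spikes(tr); b <- detect_spikes(tr)
  expect_identical(a$spike_frames, b$spike_frames)
  expect_identical(a$snr, b$snr)
})

test_that("noiseless kernel spikes are all recovered at their peak frames", {
  times <- seq(0.5, 9.5, length.out = 20)
  tr <- kernel_trace(times, amplitude = 2, polarity = -1)
  ori <- orient_trace(highpass_filter(tr, 1), "auto")
  det <- detect_spikes(ori)
  expect_length(det$spike_frames, 20)
  truth <- kernel_peak_frame(times)
  m <- match_events(det$spike_frames, truth, tol = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("per-spike SNR tracks amplitude/sigma; thresholds act monotonically", {
  times <- seq(0.5, 19.5, by = 0.5)
  sigma_tr <- 1 / 3
  tr <- kernel_trace(times, duration_s = 20, amplitude = 6 * sigma_tr,
                     noise_sd = sigma_tr, polarity = 1, seed = 44,
                     baseline = 0)
  ori <- orient_trace(highpass_filter(tr, 1), "positive")
  det3 <- detect_spikes(ori, snr_threshold = 3)
  expect_true(all(det3$snr >= 3))
  truth <- kernel_peak_frame(times)
  hit <- vapply(det3$spike_frames, function(f) any(abs(truth - f) <= 2),
                logical(1))
  expect_true(all(det3$snr[hit] >= 4 & det3$snr[hit] <= 8))
  n_at <- vapply(c(2, 3, 5), function(thr)
    length(detect_spikes(ori, snr_threshold = thr)$spike_frames), numeric(1))
  expect_true(all(diff(n_at) <= 0))
  expect_length(detect_spikes(ori, snr_threshold = 10)$spike_frames, 0)
  # spikes respect the refractory separation invariant
  expect_true(all(diff(det3$spike_frames) >= det3$refractory_frames))
})

test_that("parameter recovery: recall and precision >= 0.95 at SNR >= 5", {
  cfg <- neuronal_sim_config(n_cells = 1, height = 48, width = 48,
                             rate_independent_hz = 2, rate_network_hz = 0,
                             noise = "gaussian", noise_sigma = 2.3,
                             duration_s = 10, seed = 45)
  sim <- simulate_neuronal_movie(cfg)
  tr <- extract_trace(sim$movie, sim$rois, "cell1")
  ori <- orient_trace(highpass_filter(tr, 1), "auto")
  det <- detect_spikes(ori, snr_threshold = 3)
  expect_gt(mean(det$snr), 5)
  truth <- kernel_peak_frame(sim$truth$spike_times$cell1)
  m <- match_events(det$spike_frames, truth, tol = 2)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("false positives: zero without noise, symmetric under sign flips", {
  # pure kernel spikes carry no noise, so sigma = 0 and nothing is detected
  clean <- kernel_trace(1:5, duration_s = 8, amplitude = 2, polarity = 1,
                        baseline = 0)
  expect_equal(false_positive_control(clean), 0)
  # exchangeability as a deterministic identity: the inverted-trace control
  # on a trace equals native detection on its negation, for every seed
  for (s in seq_len(6)) {
    v <- withr::with_seed(100 + s, stats::rnorm(5000))
    tr <- highpass_filter(voltimg:::new_trace(v, 500, "n"), 1)
    pos <- voltimg:::new_trace(tr$values, 500, "n")
    neg <- voltimg:::new_trace(-tr$values, 500, "n")
    expect_identical(false_positive_control(pos),
                     length(detect_spikes(neg)$spike_frames))
    expect_identical(false_positive_control(neg),
                     length(detect_spikes(pos)$spike_frames))
  }
})

test_that("fp levels at the module's reference noise ladder are recorded", {
  # sigma in {0.5, 1, 2} x amplitude / 6 on a fixed seed
  amp <- 2
  fps_out <- vapply(c(0.5, 1, 2) * amp / 6, function(sg) {
    tr <- kernel_trace(seq(0.4, 9.6, by = 0.5), amplitude = amp,
                       noise_sd = sg, polarity = -1, seed = 46)
    ori <- orient_trace(highpass_filter(tr, 1), "auto")
    false_positive_control(ori)
  }, numeric(1))
  expect_true(all(fps_out >= 0))
  expect_true(all(is.finite(fps_out)))
})

test_that("snr_trace rescales exactly and matches per-spike SNR", {
  tr <- voltimg:::new_trace(c(rep(0, 50), 6, rep(0, 50)), 500, "x")
  st <- snr_trace(tr, 2)
  expect_equal(max(st$values), 3.0)
  expect_equal(snr_trace(voltimg:::new_trace(rep(0, 10), 500, "z"), 1)$values,
               rep(0, 10))
  spk <- kernel_trace(seq(0.5, 9.5, by = 1), amplitude = 2, noise_sd = 0.3,
                      polarity = 1, seed = 47, baseline = 0)
  ori <- orient_trace(highpass_filter(spk, 1), "positive")
  det <- detect_spikes(ori)
  sg <- estimate_noise(ori)
  expect_equal(max(snr_trace(ori, sg)$values), max(det$snr),
               tolerance = 0.05 * max(det$snr))
})

test_that("templates fall back and detection results serialize", {
  # two events only -> low-confidence analytic fallback
  tmpl <- build_template(kernel_trace(c(1, 2), amplitude = 2, polarity = 1,
                                      baseline = 0)$values,
                         peaks = kernel_peak_frame(c(1, 2)) + 1L,
                         halfwidth = 4, fps = 500)
  expect_true(tmpl$low_confidence)
  expect_equal(max(tmpl$waveform), 1)
  tr <- kernel_trace(seq(1, 9, by = 1), amplitude = 2, noise_sd = 0.3,
                     polarity = 1, seed = 48, baseline = 0)
  det <- detect_spikes_with_fp(orient_trace(highpass_filter(tr, 1), "positive"))
  expect_false(is.na(det$fp_count))
  path <- withr::local_tempfile(fileext = ".json")
  write_detection(det, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$spike_frames, det$spike_frames)
  expect_equal(back$fp_count, det$fp_count)
})
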
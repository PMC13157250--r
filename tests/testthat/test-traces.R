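# Trace extraction and trace-level statistics: mean-over-mask, donut SBR,
# high-pass, rolling-mean detrend/smooth, delta-F/F.

test_that("extract_trace is the mean over the mask, per frame", {
  mov <- const_movie(7, 8, 8, 10)
  mask <- matrix(FALSE, 8, 8); mask[2:3, 2:3] <- TRUE
  expect_equal(extract_trace(mov, mask)$values, rep(7, 10))
  # one-pixel mask returns that pixel's series
  frames <- array(0, c(4, 4, 5)); frames[2, 3, ] <- 1:5
  mov2 <- gevi_movie(frames, acquisition_meta(500, 0.01))
  m1 <- matrix(FALSE, 4, 4); m1[2, 3] <- TRUE
  expect_equal(extract_trace(mov2, m1)$values, as.numeric(1:5))
  expect_error(extract_trace(mov2, matrix(FALSE, 4, 4)), "empty")
})

test_that("noiseless simulated trace matches the analytic cell trace", {
  cfg <- neuronal_sim_config(n_cells = 1, height = 48, width = 48,
                             rate_independent_hz = 2, rate_network_hz = 0,
                             noise = "none", duration_s = 2, seed = 31)
  sim <- simulate_neuronal_movie(cfg)
  tr <- extract_trace(sim$movie, sim$rois, "cell1")
  analytic <- kernel_trace(sim$truth$spike_times$cell1, duration_s = 2,
                           amplitude = 0.05 * 40, baseline = 40)
  expect_equal(tr$values, analytic$values, tolerance = 1e-6)
})

test_that("donut mask geometry: annulus bounds, exclusions, area", {
  m <- matrix(FALSE, 64, 64)
  rr <- row(m); cc <- col(m)
  m[(rr - 32)^2 + (cc - 32)^2 <= 25] <- TRUE   # disk r = 5
  rs <- roi_set(list(cell = m), kind = "neuron")
  d <- donut_mask(rs, "cell", scale = 2, gap = 1)
  expect_false(any(d & m))
  dist <- sqrt((rr - 32)^2 + (cc - 32)^2)
  r_eq <- sqrt(sum(m) / pi)
  expect_true(all(dist[d] <= 2 * r_eq + 1e-9))
  expect_true(all(dist[d] >= 5))   # outside the cell radius
  # area close to the ideal annulus pi * ((2 r)^2 - r_in^2)
  r_in <- min(dist[d])
  ideal <- pi * ((2 * r_eq)^2 - r_in^2)
  expect_lt(abs(sum(d) - ideal) / ideal, 0.15)
  # two adjacent cells exclude each other
  m2 <- matrix(FALSE, 64, 64); m2[(rr - 32)^2 + (cc - 44)^2 <= 25] <- TRUE
  rs2 <- roi_set(list(a = m, b = m2), kind = "neuron")
  da <- donut_mask(rs2, "a")
  expect_false(any(da & m2))
})

test_that("SBR: uniform movie gives 1, constant contrast gives the ratio", {
  mov <- const_movie(13, 16, 16, 5)
  cell <- matrix(FALSE, 16, 16); cell[6:8, 6:8] <- TRUE
  donut <- matrix(FALSE, 16, 16); donut[2:4, 2:4] <- TRUE
  expect_equal(compute_sbr(mov, cell, donut), 1.0)
  frames <- array(10, c(16, 16, 5))
  frames[6:8, 6:8, ] <- 50
  mov2 <- gevi_movie(frames, acquisition_meta(500, 0.01))
  expect_equal(compute_sbr(mov2, cell, donut), 5.0)
  # invariant to positive rescaling
  mov3 <- gevi_movie(frames * 3.7, mov2$meta)
  expect_equal(compute_sbr(mov3, cell, donut), 5.0)
  expect_error(compute_sbr(mov2, cell, cell), "disjoint")
})

test_that("simulated SBR with Poisson noise lands near baseline/background", {
  cfg <- neuronal_sim_config(n_cells = 2, height = 96, width = 96,
                             baseline = 40, background = 10,
                             noise = "poisson", fps = 100, duration_s = 10,
                             seed = 32)
  sim <- simulate_neuronal_movie(cfg)
  d <- donut_mask(sim$rois, "cell1")
  sbr <- compute_sbr(sim$movie, sim$rois$masks$cell1, d)
  expect_equal(sbr, 4.0, tolerance = 0.05 * 4)
})

test_that("high-pass removes slow content, preserves fast, kills constants", {
  fps <- 500
  const <- voltimg:::new_trace(rep(5, 2000), fps, "c")
  expect_lt(max(abs(highpass_filter(const, 1)$values)), 1e-9)

  t <- (0:4999) / fps
  mix <- voltimg:::new_trace(sin(2 * pi * 0.1 * t) +
                               0.3 * sin(2 * pi * 100 * t), fps, "m")
  y <- highpass_filter(mix, 1)$values
  amp_at <- function(x, f) {
    n <- length(x)
    Mod(sum(x * exp(-2i * pi * f * (0:(n - 1)) / fps))) * 2 / n
  }
  expect_lt(amp_at(y, 0.1), 1 / 20)           # slow attenuated >= 20x
  expect_equal(amp_at(y, 100), 0.3, tolerance = 0.05 * 0.3)
  expect_lt(abs(mean(y)), 1e-6 * stats::sd(mix$values))
  # linearity: a DC offset on a kernel trace filters to the same output
  k <- kernel_trace(1, duration_s = 4, baseline = 0)
  k7 <- voltimg:::new_trace(k$values + 7, fps, "k")
  expect_equal(highpass_filter(k7, 1)$values, highpass_filter(k, 1)$values,
               tolerance = 1e-9)
  expect_error(highpass_filter(voltimg:::new_trace(1:100, 100, "x"), 60),
               "Nyquist")
})

test_that("rolling-mean detrend: constants to zero, bleach slope removed", {
  fps <- 100
  const <- voltimg:::new_trace(rep(8, 1000), fps, "c")
  expect_equal(rolling_mean_detrend(const, 1.5)$values, rep(0, 1000))

  t <- (0:999) / fps
  bleach <- voltimg:::new_trace(40 * exp(-t / 10), fps, "b")
  naive <- bleach$values / mean(bleach$values) - 1
  det <- rolling_mean_detrend(bleach, 1.5)$values
  slope <- function(v) abs(stats::coef(stats::lm(v ~ t))[2])
  expect_lt(slope(det), 0.05 * slope(naive))
  # a fast spike's fractional amplitude survives the division
  sp <- kernel_trace(5, duration_s = 10, fps = 500, amplitude = 0.05 * 40,
                     baseline = 40)
  dsp <- rolling_mean_detrend(sp, 1.5)$values
  expect_equal(min(dsp), -0.05, tolerance = 0.1)
})

test_that("rolling-mean smooth: identity at one frame, 1/sqrt(w) noise law", {
  fps <- 100
  tr <- voltimg:::new_trace(stats::rnorm(5000), fps, "n")
  expect_identical(rolling_mean_smooth(tr, 0.005)$values, tr$values) # w = 1
  expect_equal(rolling_mean_smooth(const_trace <- voltimg:::new_trace(
    rep(2, 500), fps, "c"), 0.03)$values, rep(2, 500))
  withr::with_seed(33, {
    noise <- voltimg:::new_trace(stats::rnorm(20000), fps, "w")
  })
  sm <- rolling_mean_smooth(noise, 0.03)  # w = 3 frames
  expect_equal(stats::sd(sm$values), 1 / sqrt(3), tolerance = 0.05 / 0.577)
})

test_that("dff: exact example, zero mean, scale invariance", {
  tr <- voltimg:::new_trace(c(9, 11), 100, "x")
  expect_equal(dff(tr)$values, c(-0.1, 0.1))
  expect_equal(dff(voltimg:::new_trace(rep(4, 10), 100, "c"))$values, rep(0, 10))
  withr::with_seed(34, {
    v <- stats::runif(200, 10, 20)
  })
  a <- dff(voltimg:::new_trace(v, 100, "a"))$values
  b <- dff(voltimg:::new_trace(3.1 * v, 100, "b"))$values
  expect_equal(a, b)
  expect_equal(mean(a), 0)
  expect_error(dff(voltimg:::new_trace(c(-5, -6), 100, "n")), "positive")
})

test_that("noiseless simulated spike: dff minimum near -a plus the mean shift", {
  tr <- kernel_trace(2, duration_s = 10, amplitude = 0.05 * 40, baseline = 40)
  d <- dff(tr)$values
  expect_lt(abs(min(d) - (-0.05)), 0.005)
})

test_that("trace ops preserve length and record provenance", {
  tr <- kernel_trace(c(1, 2), duration_s = 4, noise_sd = 0.1)
  out <- highpass_filter(rolling_mean_smooth(rolling_mean_detrend(tr, 1.5),
                                             0.03), 1)
  expect_length(out$values, length(tr$values))
  expect_equal(length(out$steps), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(out, path)
  lines <- readLines(path, n = 3)
  expect_true(any(grepl("steps:", lines)))
})
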
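# Shared fixtures: small deterministic movies and traces built in code.

# tiny constant movie
const_movie <- function(value = 5, h = 8, w = 8, n_t = 10, fps = 500) {
  gevi_movie(array(value, c(h, w, n_t)), acquisition_meta(fps, n_t / fps))
}

# single-cell trace of biexponential kernel spikes on a flat baseline
kernel_trace <- function(spike_times_s, duration_s = 10, fps = 500,
                         amplitude = 2, baseline = 40, noise_sd = 0,
                         polarity = -1, seed = 1) {
  n <- round(duration_s * fps)
  kern <- spike_kernel(1, 5, fps)
  v <- numeric(n)
  for (ts in spike_times_s) {
    f0 <- floor(ts * fps) + 1L
    if (f0 > n) next
    idx <- f0:min(n, f0 + length(kern) - 1L)
    v[idx] <- v[idx] + polarity * amplitude * kern[seq_along(idx)]
  }
  if (noise_sd > 0) {
    v <- v + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  voltimg:::new_trace(baseline + v, fps, "synthetic")
}

# frame index (0-based) of the kernel optical peak for a spike at time ts
kernel_peak_frame <- function(ts, fps = 500, tau_r_ms = 1, tau_d_ms = 5) {
  tr <- tau_r_ms / 1000; td <- tau_d_ms / 1000
  tp <- log(td / tr) * tr * td / (td - tr)
  floor(ts * fps) + round(tp * fps)
}

# shallow config modification (keeps the class)
within_cfg <- function(cfg, ...) {
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  cfg
}

# match detected frames against true frames within a tolerance
match_events <- function(detected, truth, tol = 2) {
  tp <- sum(vapply(detected, function(f) any(abs(truth - f) <= tol), logical(1)))
  found <- sum(vapply(truth, function(f) any(abs(detected - f) <= tol), logical(1)))
  list(precision = if (length(detected)) tp / length(detected) else NA_real_,
       recall = if (length(truth)) found / length(truth) else NA_real_)
}
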
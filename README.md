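# voltimg

Analysis of genetically encoded voltage indicator (GEVI) fluorescence
movies from developing zebrafish — spiking neurons imaged at hundreds of
frames per second and the embryonic heart imaged at ~100 fps with
contractions pharmacologically arrested.

Optical voltage recordings pose a specific chain of problems: the signal is
a few percent of baseline fluorescence, riding on photobleaching, rigid
sample jitter and shot noise; spikes must be separated from noise with an
explicit, auditable acceptance rule; and claims about network synchrony or
cardiac conduction are only as good as the detection that feeds them.
`voltimg` implements that chain end to end, together with synthetic movie
generators with full ground truth so every stage can be validated by
parameter recovery rather than by eye.

## What it computes

* **Rigid motion correction** — per-frame translation by mean-subtracted
  FFT cross-correlation against a median template, refined to 1/10 px by
  local upsampled DFT; applied with bilinear interpolation.
* **Trace statistics** — mean-over-ROI traces; ΔF/F = (F − F̄)/F̄;
  zero-phase 1 Hz Butterworth high-pass; 1.5 s rolling-mean
  photobleaching correction (divisive) and 30 ms rolling-mean smoothing;
  signal-to-background ratio SBR = mean cell fluorescence / mean
  fluorescence of a donut mask of twice the cell diameter.
* **Spike detection** — two-pass matched-template detection: candidates
  above 3.5σ (σ = 1.4826·MAD of the spike-free baseline) build an
  empirical template; greedy peeling on the matched-filter output with a
  refractory rule; each spike kept only if its SNR (peak amplitude / σ)
  reaches the threshold (default 3). A false-positive control reruns the
  identical detector on the inverted trace.
* **Synchrony** — Pearson correlation matrices of firing rates in 10 ms
  bins, with within/between-group summaries; silent cells give missing
  (never zero) entries.
* **Cardiac metrics** — chamber ΔF/F traces; beat rate; APD50; activation
  times as interpolated 50% upstroke crossings; atrial→ventricular
  conduction delay; voltage-time footprint maps (per-pixel temporal
  maximum ΔF/F in a 200 ms window) with time-of-peak.
* **Simulators** — ring-shaped spiking neurons with shared-event
  synchrony, bleaching, motion and shot noise; a two-chamber heart with
  chamber-specific action potentials, an intra-chamber activation wave and
  a fixed A–V delay. Both emit movies, ROI label images and ground-truth
  JSON, reproducibly from a single seed.

## Worked example

```r
library(voltimg)

cfg <- neuronal_sim_config(n_cells = 3, height = 64, width = 64,
                           noise = "gaussian", noise_sigma = 2.3,
                           duration_s = 10, seed = 1)
sim <- simulate_neuronal_movie(cfg)
sim$movie
#> gevi_movie: 5000 frames of 64 x 64 @ 500 fps (10 s), range [0, 51.01]

tr  <- extract_trace(sim$movie, sim$rois, "cell1")
ori <- orient_trace(highpass_filter(tr, cutoff_hz = 1), "auto")
det <- detect_spikes_with_fp(ori, snr_threshold = 3)
det
#> spike_detection 'cell1': 16 spike(s), sigma = 0.2883, threshold SNR 3
#>   SNR: median 6.61, range [5.28, 8.54]
#>   inverted-trace false positives: 0
length(sim$truth$spike_times$cell1)   # ground truth agrees
#> [1] 16

compute_sbr(sim$movie, sim$rois$masks$cell1, donut_mask(sim$rois, "cell1"))
#> [1] 4.000119

synchrony_matrix(sim$truth$spike_times, duration_s = 10)
#> synchrony_matrix: 3 cells, 1000 bins of 10 ms
#>       cell1 cell2 cell3
#> cell1 1.000 0.425 0.582
#> cell2 0.425 1.000 0.538
#> cell3 0.582 0.538 1.000
```

The detector found all 16 true spikes of cell 1 with median SNR 6.6 and no
inverted-trace false positives; the SBR matches the simulated 40/10
cell/background contrast; and the off-diagonal correlations reflect the
shared network events the generator injected (participation 0.8).

The cardiac side, equally compactly:

```r
csim <- simulate_cardiac_movie(cardiac_sim_config(seed = 1))
ea <- detect_cardiac_events(chamber_trace(csim$movie, csim$rois, "atrium"))
ev <- detect_cardiac_events(chamber_trace(csim$movie, csim$rois, "ventricle"))
ea
#> cardiac_events 'atrium': 20 beat(s), rate 2 Hz, APD50 80.1 ms (median)
ev
#> cardiac_events 'ventricle': 19 beat(s), rate 2 Hz, APD50 185 ms (median)
av_delay(ea, ev)
#> A-V delay: 0.1065 s (median of 19 matched beats; 0 V / 1 A unmatched)
```

The simulated conduction delay was 0.100 s and the configured APDs were
80 ms (atrium) and 200 ms (ventricle): both are recovered within one frame
/ 10%.

Config-driven pipelines (`run_simulation()`, `run_neuronal()`,
`run_cardiac()`) wrap these stages, write JSON/CSV/TIFF result bundles plus
a run manifest, and are exposed on the command line through
`exec/voltimg.R` (`simulate`, `neuronal`, `cardiac` subcommands).

## Further reading

The methods vignette (`vignettes/voltimg-methods.Rmd`) documents the
simulator models and their defaults, the numerical choices in every stage
(filter padding, detrend edge handling, peeling in the matched filter,
registration without spectral whitening), what the synthetic benchmarks
demonstrate and what they cannot, and the package's known limitations.
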
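Package: voltimg
Title: Voltage-Imaging Analysis for Developing Zebrafish Neurons and Heart
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for genetically encoded voltage indicator
    (GEVI) fluorescence movies of developing zebrafish. Provides rigid
    (translation-only) motion correction by subpixel phase correlation,
    ROI trace extraction with donut-mask signal-to-background ratios,
    zero-phase high-pass filtering and rolling-mean detrending, matched
    template spike detection with a per-spike SNR acceptance rule and an
    inverted-trace false-positive control, spike-train synchrony via
    Pearson correlation of binned firing rates, and cardiac optical
    mapping (delta-F/F traces, beat rate, action-potential duration,
    atrioventricular conduction delay, voltage-time footprint maps).
    Includes synthetic neuronal and cardiac movie generators with full
    ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tiff,
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
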
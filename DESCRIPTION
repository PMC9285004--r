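Package: mealfp
Title: Local Field Potential and Seizure-Like Event Analysis for High-Density
    Multielectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing local field potential (LFP) activity recorded
    from high-density multielectrode arrays (64x64 electrode grids, 60 um
    pitch) on acute brain slices. Provides an open HDF5 container for
    multichannel voltage recordings with selective channel/time reads,
    anti-aliased downsampling, zero-phase digital filtering, amplitude
    spectra and EEG-band power estimates, threshold/duration LFP peak
    detection with per-channel and channel-group summary measures, an
    unsupervised seizure-like event detector combining short-time Fourier
    transform magnitudes and voltage-threshold activity streams, and network
    metrics for detected events (initiation site, maximum spread distance,
    duration, and propagation speed). Includes a seedable synthetic-recording
    generator with ground truth for validation, and a command-line interface
    for batch workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: HDF5 (libhdf5 >= 1.10)
Config/testthat/edition: 3
NeedsCompilation: yes
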
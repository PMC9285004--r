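---
title: "LFP peak detection and seizure-envelope analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LFP peak detection and seizure-envelope analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealfp)
```

`mealfp` analyses local field potentials (LFP) recorded from high-density
multielectrode arrays — 64 × 64 electrode grids at 60 μm pitch on which an
acute brain slice rests — with a focus on epileptiform activity: counting
and characterising LFP events per channel and per region, and detecting
seizure-like events (SLEs) together with their spatial spread, duration,
and propagation speed. This vignette documents the models and the design
choices behind each step, and what the synthetic-data tests do and do not
establish about real recordings.

## Recording model and units

A recording is a samples × channels matrix of extracellular voltage in
millivolts with a sampling rate in Hz, an electrode pitch in micrometers
(default 60), and a channel table mapping each trace column to a grid
position: 1-based `(row, col)` and the linear index
`(row − 1) × 64 + col` in 1..4096. Time is measured in seconds from the
recording start; analysis intervals are half-open `[start, end)` so
adjacent intervals partition samples without overlap. On disk, recordings
use a documented open HDF5 layout (`/recording/traces` as float32 with
channels contiguous, scalar rate/pitch/start-time, and an integer channel
table); vendor exports can be converted into this layout by thin adapters.
Storing traces as 32-bit floats keeps files at half the in-memory size and
preserves voltages to ~1e−7 relative, far below the noise floor of these
recordings. Working files are produced by downsampling acquisition-rate
data (typically 10 kHz) to an LFP-band rate (typically 300 Hz): a
zero-phase FIR anti-alias filter with cutoff at 0.4 × the output rate
followed by integer-factor decimation, `q = floor(source/target)`. Only
integer factors are used, so the achieved rate `source/q` is reported and
may differ from the request; resampling to arbitrary rates would require
interpolation that can colour the noise spectrum.

## LFP peaks

An LFP peak is a strict local voltage extremum that deviates from the
channel baseline by at least a threshold (default 0.07 mV) and whose full
width at the baseline level is at least a minimum duration (default
0.02 s). Three operational choices deserve note:

* **Baseline.** The baseline is the median of the analysed trace segment
  (configurable, or an explicit level). The median is robust to sparse
  large events riding on a stationary noise floor, which is exactly the
  regime of interictal activity.
* **Width.** The width is the interval between the two baseline
  crossings bracketing the apex, linearly interpolated between samples.
  The width is therefore a property of the excursion and does not depend
  on the detection thresholds; this makes peak counts provably
  non-increasing in both the threshold and the minimum duration, a
  property the test-suite checks on parameter grids.
* **Polarity.** Maxima and minima are both detected (configurable).
  Because LFP events are commonly biphasic, two opposite-polarity apexes
  closer than the minimum duration are treated as one event and the
  larger-amplitude apex is kept, with a deterministic
  amplitude-then-time-then-polarity ordering so results never depend on
  evaluation order.

Per channel, the analysed interval yields the peak count, count per
second, mean peak amplitude, and mean peak width; channels with no peaks
report *undefined* (not zero) means so that group averages are not biased
toward zero. Band powers (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30,
gamma 30–100 Hz, clipped to Nyquist — conventional EEG edges, since no
canonical slice-LFP convention exists) are Welch power-spectral densities
(1 s Hann segments, 50 % overlap) averaged within each band and reported
in V²/Hz.

Group summaries over named, pairwise-disjoint channel groups report the
total channel count, the number of *active* channels (strictly more than
20 peaks in the interval), the summed peak rate, and the mean amplitude /
duration both over all channels and over the top-N most active channels
(default N = 20, ties at the boundary resolved toward the lower linear
index for determinism).

## Seizure-envelope detection

Each channel is processed independently and unsupervised:

1. **Baseline window.** A 60 s reference window with no LFP activity,
   seizure-like activity, or electrical noise spikes is chosen from the
   first 5 minutes (or the whole trace, with a warning, when shorter).
   Candidates on a 10 s grid are scored by the count of samples deviating
   more than 6 robust (MAD-based) SDs from the search-region median plus
   the window variance normalised by the median candidate variance; the
   earliest minimal score wins. The two score terms capture the two
   failure modes — isolated electrical spikes and sustained activity —
   and the deterministic tie-break makes reanalysis reproducible.
2. **Spectral stream.** A short-time Fourier transform with 1 s Hann
   segments and no overlap; per segment, the magnitudes of all frequency
   components below half the sampling rate are summed. A bin is active
   when this sum exceeds the baseline mean + 6 baseline SDs.
3. **LFP stream.** Peaks with threshold 6 × the baseline voltage SD and a
   fixed 0.035 s minimum width (amplitudes measured from the baseline
   window mean); samples within each peak's width are active.
4. **Continuity.** Each binary stream is smoothed by two centred moving
   means. A point is inside a region when the short-window density
   reaches 0.1; two regions merge when the long-window density stays at
   or above 0.05 throughout the gap. Window lengths are counted in each
   stream's own datapoints: 30/500 samples for the LFP stream and 5/30
   bins for the spectral stream — the sample-stream defaults rescaled to
   the 1 s bin grid, since 500 one-second bins would span more than
   typical inter-seizure spacing.
5. **Envelopes.** Overlaps of spectral and LFP continuity regions lasting
   at least 10 s become seizure envelopes. The envelope end is the end of
   the overlap. The start is refined to sample resolution: the first
   crossing of the trace's moving-RMS amplitude envelope (0.25 s window)
   above the same 6-SD voltage threshold, searched from one spectral bin
   before the overlap start. Without this refinement every start would be
   quantised to the 1 s STFT bin, which is too coarse to resolve onset
   lags between nearby channels; with it, the detection delay is nearly
   constant across channels (it depends on the discharge's amplitude
   ramp, not the channel), so between-channel lag differences — the
   quantity the propagation metrics need — are preserved.

Channels whose baseline has zero variance (dead or disconnected inputs)
are skipped with a warning rather than failing the recording.

## Network metrics

Within a selected analysis window, the channels of a group whose
envelopes intersect the window *participate* in the SLE. The metrics
follow the standard definitions on the electrode grid:

* **Initiation.** The channel with the earliest (clipped) envelope start;
  channels starting within `tie_tolerance_s` of it are co-initiators.
  The tolerance default is 0.25 s. A tolerance tied to the 1 s spectral
  bin would make initiator membership depend on where a bin boundary
  falls, and on a 20 × 20 grid a wave faster than ~1,500 μm/s would make
  *every* channel a co-initiator and leave the propagation speed
  undefined; 0.25 s is comfortably above the onset-estimation jitter yet
  resolves the wavefronts of interest. It is configurable for slower,
  larger-scale preparations.
* **Maximum spread.** `sqrt((Δrow)² + (Δcol)²) × pitch`, maximised over
  initiator–participant pairs.
* **Duration.** Envelope end minus start per participating channel
  (clipped to the window; the earliest envelope per channel), with group
  mean and maximum.
* **Propagation speed.** Maximum spread distance divided by the mean
  onset lag of *non-initiator* participants relative to the earliest
  onset. Initiators are excluded from the mean so near-zero lags do not
  deflate it; when no non-initiator participates, or the mean lag is
  zero, the speed is reported as undefined rather than as an infinite or
  missing number.

One property of this statistic is worth stating plainly: for a radial
wave of physical speed v crossing a filled region, the statistic
converges to `v × d_max / mean(d)` over the non-initiator channels —
about 1.5–1.9 × v for a filled square — because the maximum distance sits
in the numerator while the *mean* lag sits in the denominator. It is a
perfectly useful comparative index (and is how the field reports seizure
spread rates), but it is not an unbiased estimator of wavefront velocity.
The synthetic-recovery tests therefore compare the detector's output
against the same statistic evaluated on the generator's true onsets,
which isolates detection error from this geometric factor;
`truth_network_metrics()` exposes that reference value.

## Synthetic recordings and what the tests show

The generator builds grid recordings from three seeded components:
per-channel Gaussian noise (default SD 0.02 mV at 300 Hz); interictal
spikes — biphasic half-sine transients (default 0.15 mV, 0.05 s) at
Poisson times; and a traveling SLE — each channel at distance d from the
origin starts at `onset + d/speed` and receives a sinusoidal discharge
(default 8 Hz, 0.5 mV, 30 s) with a 2 s linear amplitude ramp and Poisson
spike riders, so both the spectral and the LFP branch of the detector see
sustained activity. Every channel derives its own RNG substream from the
master seed and its linear index, making output independent of iteration
order. Defaults mirror a low-Mg²⁺ ictogenesis recording on a 400-channel
(20 × 20) patch: ~0.02 mV noise floor, a focal SLE spreading at
~1,000 μm/s, discharge amplitudes an order of magnitude above noise.

The validation suite establishes, under these conditions: exact
equivalence of the peak detector with an exhaustive brute-force oracle on
randomized spiky traces; zero false seizure envelopes on pure-noise
recordings at default thresholds; 20/20 detection of injected 30 s SLEs
at 10 × the noise SD with start errors ≤ 2 s and duration errors ≤ 5 s,
while 8 s bursts are never reported; and recovery of the origin channel
and of the propagation-speed and duration statistics to within ±20 %
across wave speeds of 250–2,000 μm/s and durations of 15–60 s (test
problem sizes: 1,000 oracle traces up to 3,000 samples; 20 noise seeds of
120 s × 4 channels; 20 sensitivity seeds; a 4 × 3 × 3
speed × duration × seed recovery grid on the 20 × 20 patch).

What the synthetic model deliberately omits: 1/f background spectra and
line noise; spatially correlated noise; anisotropic or saltatory
propagation; amplitude gradients with distance; pre-ictal discharges
blending into onset; and electrode drift. Passing these tests therefore
demonstrates the correctness of the *algorithms* under controlled
phenomenology, not detector performance on any particular slice
preparation — on real data the stated defaults are starting points, and
low signal-to-noise recordings may need manual verification of a few
channel envelopes, exactly as with any unsupervised detector.

## Numerical notes

* FFT amplitude spectra are one-sided and scaled so a sine of amplitude A
  peaks at A; Parseval consistency is tested to 1e−6.
* Filters are 4th-order Butterworth applied forward–backward (zero
  phase); a band-pass upper edge at or above Nyquist (e.g. 40–150 Hz at a
  300 Hz working rate) is clipped to 0.99 × Nyquist with a warning.
  Traces are reflection-padded before `filtfilt` so edge transients stay
  out of the analysis window.
* All interval logic is half-open and in seconds; the STFT discards a
  trailing partial segment; moving means truncate and renormalise their
  windows at the trace edges.
* Degenerate inputs (constant traces, empty groups, waves leaving the
  recording window) raise validation errors rather than propagating NaN;
  the one deliberate exception is the per-channel zero-variance skip
  during recording-level envelope detection, which warns instead so one
  dead electrode cannot abort a 400-channel analysis.
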
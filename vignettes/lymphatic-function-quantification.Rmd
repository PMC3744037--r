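---
title: "Quantifying lymphatic transport function from NIR fluorescence imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lymphatic transport function from NIR fluorescence imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphnir)
```

## The measurement problem

Collecting lymphatic vessels pump fluid in discrete boluses ("packets"):
each contraction of a lymphangion — the valve-bounded contractile segment —
propels a slug of lymph downstream. When a near-infrared tracer such as
indocyanine green (ICG) bound to albumin is injected intradermally, these
packets become visible as transient fluorescence pulses moving through the
downstream collecting vessels, and the pumping behaviour of the vessel can
be read off a camera pointed at the tissue. In the rat tail — a standard
model because its two collecting vessels run predictably in parallel — an
imaging window is centred 10 cm downstream of a tail-tip injection and
recorded continuously at 50 ms frame intervals for 20 minutes.

From such recordings the package computes, independently for both vessels:

* **Transport time** — the time for the tracer front to travel from the
  injection site to the imaging window, measured as the fluorescence
  arrival time in the vessel's ROI.
* **Packet frequency** — contractions per minute passing the field of
  view.
* **Packet velocity** — advection speed of packets through the field of
  view, in mm/s.

Frequency and velocity are evaluated in two 100-second analysis segments:
an **arrival segment** starting 60 s after that vessel's fluorescence
arrival (the transient response to the fluid bolus) and a **steady-state
segment** starting 10 min after injection. The vessel whose fluorescence
arrives first is labelled **dominant**, the other **non-dominant**; in
longitudinal designs the labels are frozen at the week-0 session.

Every estimator in the package is validated against a synthetic-data
generator that knows its own ground truth, because in-vivo recordings come
with no reference answer.

## The per-session pipeline

`analyze_session()` composes the following stages; each is exported and
testable on its own.

### ROI traces and the noise reference

`extract_trace()` reduces a calibrated video stack to the mean ROI
intensity per frame. Background statistics are pooled over all pixel
samples of the background ROI in the first 10 s of the recording — before
tracer can reach a window 10 cm downstream — so `background_sd` estimates
the *single-pixel* noise SD. This convention keeps detection thresholds
comparable between trace-level and video-level data: averaging over an ROI
suppresses noise in the trace, and a threshold expressed in single-pixel
SDs is then conservative.

### Arrival detection

The arrival marker is a sustained 20% intensity rise. Concretely: baseline
is the median of the first 10 s; the threshold is
`max(1.2 * baseline, baseline + 5 * background_sd)`; the trace must stay
above it for 1 s of consecutive samples. The absolute floor exists because
a bare relative threshold is ill-posed when the pre-arrival baseline is
near zero — 20% of almost nothing is noise.

A fixed rise threshold necessarily *lags* the true onset by roughly
`-tau * ln(1 - rise/plateau)` for a saturating rise with time constant
`tau`. The reported arrival time therefore refines the crossing by tangent
back-extrapolation: a line is fitted over the 2 s following the crossing
and intersected with the baseline. For an ideal step the fit has zero
slope and the correction is skipped, so step-like arrivals return the
crossing time exactly; the correction is also capped at twice the fit
window so a pathological fit cannot drag the estimate far. On simulated
healthy sessions this keeps arrival estimates within ±2 s of the true
onset for both the bright and the dim vessel.

### Detrending and packet detection

Packets ride on a slowly saturating "free-flow" baseline. A running-median
filter (window 30 s, `detrend_trace()`) removes the baseline without
ringing; the window is an order of magnitude wider than a packet pulse and
narrower than the baseline's rise, so pulse amplitudes survive within 15%.

Packets are then strict local maxima of the (lightly smoothed, SD 0.15 s)
detrended segment with topographic prominence at least
`max(5 * background_sd, 0.1 * segment dynamic range)` and at least 1 s
peak separation. The exact rules — including the walk-to-higher-sample
prominence definition and the greedy, value-ordered separation filter —
are frozen in `find_peaks()` documentation so that an independent
exhaustive implementation reproduces them; the test suite holds the
operator to that oracle on a thousand random traces. The pre-smoothing
matters: raw per-sample noise would otherwise generate spurious local
maxima whose prominence can reach ~7 noise SDs in a 2000-sample segment,
while smoothing with a kernel much narrower than a pulse costs only ~10%
of pulse amplitude.

Packet frequency is simply the detected count over the segment duration,
in packets/min.

### Packet velocity

The vessel ROI is split into 5 equal axial sub-ROIs (`subdivide_vessel_roi()`)
spanning 10 mm. Packets are detected in the middle sub-ROI; for each, the
pulse peak time in every sub-ROI is located within a window around the
reference peak (half-width capped at 10 s and at half the distance to the
neighbouring packets) and refined by parabolic interpolation through the
three samples at the maximum, giving sub-frame resolution. Velocity is the
least-squares slope of axial position against front time. Packets whose
front times are not strictly ordered along the vessel, or whose regression
R² falls below 0.8, are discarded and counted — this absorbs overlapping
packets and truncated transits without biasing the kept ones — and the
segment value is the median over kept packets. A whole-segment
cross-correlation estimator (`method = "xcorr"`) is available as a
packet-free cross-check.

At 0.05 s frame intervals and the velocities of interest
(0.5–5 mm/s), the 2 mm sub-ROI spacing translates to inter-ROI lags of
0.4–4 s, i.e. 8–80 frames, comfortably resolvable; validation across that
whole range recovers velocity within 10% in ≥90% of runs.

### Dominance

The first-arriving vessel is dominant. If arrivals differ by less than one
frame interval the tie is broken by the higher mean intensity over the
first 100 s post-arrival (the dominant vessel characteristically runs
brighter); a perfect tie falls back deterministically to the first ROI and
is flagged. Only-one-vessel-detected sessions make that vessel dominant;
neither detected is an error. For follow-up weeks `analyze_session()`
copies the week-0 labels rather than reclassifying, so longitudinal
contrasts always compare like with like.

## Retention, node morphometry, and statistics

**Retention.** Tracer visibility at the injection site is tracked as
`SNR = 20 * log10((mean - background_mean) / background_sd)` with the
conventional 3 dB visibility limit. Whether such limits are historically
meant as amplitude (20 log10) or power (10 log10) ratios is often left
unstated; the package defaults to the amplitude convention and exposes
`mode = "power"`. `retention_curve()` reports per-day SNR and the last
sampled day above the limit.

**Node morphometry.** Projected two-dimensional node area is foreground
pixel count times pixel area. For grayscale microscopy the node is
segmented by Otsu threshold → largest connected component → hole fill;
this reconstruction is deliberately the plainest defensible operator since
no standard exists, and it recovers analytic ellipse areas within 5% on
noisy, blurred synthetic images.

**Statistics.** `compare_design()` runs the three standard families on the
compiled table: paired two-tail dominant-vs-non-dominant comparisons,
unpaired two-tail group comparisons (Welch by default — the safer choice
under unequal variances, with a pooled-variance switch), and paired
one-tail week-k-vs-week-0 comparisons in the direction of functional
decline (transport time up; frequency and velocity down). Bonferroni
control uses the number of comparisons in the family for the two-tail
designs and no correction (m = 1) for the one-tailed time course,
matching the protocol conventions; `m` is configurable and both raw and
adjusted p-values are always reported, since family size is a convention
rather than a fact. Transport time is a per-session quantity; the
compiled table enters it under both segment families so that each family
carries the full metric set, and its two entries are identical by
construction. Degenerate inputs follow fixed rules: zero variance with
zero effect is an undefined test (an error, not p = 1); zero variance
with a real effect returns a p = 0 sentinel flagged `degenerate`;
missing metrics are dropped pairwise with recorded counts — they are
never imputed as zeros, which would fabricate deficits.

## The synthetic-data generator

`simulate_trace()` / `simulate_video()` generate, from a single seed, two
parallel vessels carrying:

* a saturating free-flow baseline
  `plateau * (1 - exp(-(t - t_arr)/tau))` over a constant background;
* Gaussian packet pulses at gamma-renewal event times (shape 4 by
  default — lymphangion contractions are quasi-periodic, not Poisson;
  shape 1 recovers Poisson for stress tests), advected in the video at a
  constant per-vessel velocity;
* additive Gaussian noise (a shot-noise-like signal-dependent mode is
  available), quantised to integer camera counts in the video path.

Packet times are parameterised at the imaging window: a packet's event
time is the moment it enters the field of view, so the injection-to-window
transit lives entirely in `arrival_time_s`. Blob amplitudes are calibrated
so the full-vessel-ROI mean pulse height equals `packet_amplitude`,
making trace-level and video-level analyses directly comparable.

Calibration choices, made once and documented here:

* **Absolute rates and velocities.** No absolute reference values exist
  for these quantities in this preparation, only ranges consistent with
  rodent collecting lymphatics. The healthy preset uses 6 and 4
  packets/min and 2.0 and 1.5 mm/s for the dominant and non-dominant
  vessel, with arrivals at 60 s and 85 s (a 25 s offset; offsets of 20 s
  or more are the typical observation).
* **Pulse width** (`packet_width_s = 0.3` s SD): chosen so that packet
  pairs remain optically resolvable across the emulated rate range up to
  15/min — with the 5-SD prominence floor, pulses merge below ~3.3 SDs of
  separation, so a width must be narrow relative to the shortest typical
  inter-packet interval.
* **Baseline rise time** (`baseline_tau_s = 6` s): a rapid uptake
  consistent with the near-step rise seen in dominant vessels, and short
  enough that the threshold detector's onset lag stays well inside the
  ±2 s arrival accuracy the pipeline is held to.
* **Retention decay** (`retention_decay_days = 6.5`, day-0
  amplitude/noise ratio 20 → 26.02 dB): a single exponential whose
  analytic 3 dB crossing falls at 17.2 days, i.e. visibility for more
  than two weeks, sampled every 2 days.
* **Scenario presets.** `gtno` (topical nitric-oxide donor) multiplies
  the non-dominant transport time 6-fold (510 s vs 85 s), doubles the
  dominant one, and halves rates and velocities. `icg_week1` degrades all
  metrics in both vessels; its non-dominant rate (1.5/min, from 4/min) was
  set by an explicit power computation: at the design's n = 4, paired
  one-tail, the gamma-renewal counting noise of 100-s segments gives a
  paired-difference SD near 1.1 packets/min, so an encoded deficit must
  exceed ~2.2 packets/min for the significance the week-1 effect is
  documented to show. `icg_week2` degrades only the non-dominant vessel;
  `week4` and `control` equal `healthy`.

What the generator does **not** emulate: optical point-spread realism,
tissue scattering, breathing or motion artefacts, photobleaching,
vessel-diameter changes, pharmacokinetics of tracer binding, and rate or
velocity *tapering* within a session (rates are constant per segment).
Passing validation therefore demonstrates that the estimators recover
known answers under the package's noise model — not that every in-vivo
complication is handled. Motion correction in particular is deliberately
out of scope (restrained-tail recordings).

## Numerical conventions and problem sizes

* Pixel coordinates are 0-based and half-open; times are seconds since
  injection (`t0_s` covers late-started recordings); axial distances are
  mm from the injection site with the window at 100 mm.
* Stacks are stored as 16-bit integer-count TIFF with a YAML sidecar for
  calibration; integer stacks round-trip losslessly, and missing sidecar
  metadata is an error, never a default.
* Peak ties in the separation filter are broken by value, then by earlier
  sample; all operators are deterministic for fixed input, and all
  generator randomness flows from one seed, so identical seeds give
  byte-identical artifacts.
* Segments that extend past the recording are truncated and flagged; a
  late arrival segment may overlap the steady-state segment and is
  flagged rather than silently shifted.
* The validation suite runs sessions of 190–750 s (the steady-state
  segment needs 700 s) rather than the full 20-minute protocol, and
  50–100 seeds per property; these sizes were chosen as the smallest that
  exercise every code path with stable Monte-Carlo margins.

## Known limitations

* The packet and velocity operators are reconstructions of common practice
  (prominence peaks on a running-median detrend; multi-ROI front
  regression); parameters are exposed in `analysis_config()` and defaults
  justified by simulation, but other labs' operators may differ in detail.
* Full-vessel-ROI traces widen each pulse by the transit time `L/v`, so
  at high rates packets can overlap in the trace even when they are
  distinct in the vessel; frequency validation is therefore tied to the
  resolvable regime, and sub-ROI traces (as used for velocity) are the
  better view when pulses crowd.
* `snr_db` assumes a stationary background; slow background drift over
  weeks of retention imaging is not modelled.
* The statistics module implements exactly the protocol's t-test designs;
  repeated-measures or mixed-effects modelling across all weeks at once is
  out of scope.
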
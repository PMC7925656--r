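---
title: "Methods: SSVEP phase locking and traveling-wave velocity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSVEP phase locking and traveling-wave velocity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ssvepwave)
```

## The model

Repetitive visual stimulation at a gamma-band frequency $f$ evokes a scalp
EEG oscillation at $f$ (the steady-state visual evoked potential, SSVEP)
that is phase-locked to the stimulus.  The package models its spatial
organisation as a wave whose phase propagates isotropically from a single
scalp source: a channel at great-circle distance $d$ (cm) from the source
lags the source by

$$\Delta\phi(d) = \frac{2\pi f\, d}{v(f)},$$

where $v(f)$ is the phase velocity (cm/s internally, reported in m/s).
Inverting this relation per condition is the core estimator: regress the
per-channel phase lag on distance and read the velocity off the slope,
$v = 2\pi f / \text{slope}$, with wavelength $\lambda = 100\,v/f$ cm.
Distances live on a spherical head model of radius 9 cm and are computed
with the haversine form of the great-circle distance, which is
numerically stable for nearby electrodes.

Assumptions worth stating explicitly: one dominant source, isotropic
propagation (so distance from the source is a sufficient spatial
coordinate), a linear phase–distance relation over the analysed electrode
band, and narrowband stationarity of the response during stimulation.

## The analysis chain

1. **Line-noise notch** (50 Hz): a second-order IIR notch applied forward
   and backward, so the net phase response is identically zero.  The
   quality factor defaults to Q = 45; at Q = 35 the two-pass loss at
   ±2 Hz from the notch reaches 1.0 dB, just violating the design goal of
   under 1 dB outside the ±2 Hz guard band, so the default is the
   smallest round Q that meets it with margin (−0.6 dB).
2. **Decimation** 2048 → 256 Hz: a 289-tap Hamming-window FIR anti-alias
   lowpass (cutoff 115 Hz) applied as a zero-phase symmetric kernel with
   exact group-delay compensation; events and the stimulus trace are
   re-indexed consistently.
3. **Spatial filter**: spherical-spline surface Laplacian (spline order
   m = 4, 50 Legendre terms, ridge regularization λ = 1e-5), yielding a
   reference-free current-source-density estimate in µV/cm².  The
   operator annihilates any common reference shift by construction.  A
   common-average-reference option exists only for contrast experiments.
4. **Epoching**: −1 s to +3 s around each stimulus onset, grouped by
   condition frequency; epochs that would leave the recording are dropped
   with a warning.
5. **ERS maps**: Hanning STFT with a 126-sample window.  The window is
   commonly described as "500 ms", but 126 samples at 256 Hz is 492 ms;
   the sample count is treated as normative because it, not the rounded
   millisecond label, fixes the FFT grid.  The hop is 4.5 samples — the
   fractional grid is rounded per window start — which tiles a 1024-sample
   epoch with exactly 200 windows.  ERS is the percent change of
   trial-mean power at the fundamental's nearest FFT bin in each 250 ms
   window against the [−250, 0) ms baseline.  Trial-mean power enters the
   ratio first (the alternative, per-trial ratios, is config-exposed).
6. **Narrowband phase**: per condition, a Parks–McClellan equiripple FIR
   bandpass (pass $f\pm1$ Hz, stop beyond $f\pm3$ Hz, ripples 0.058 and
   $10^{-4}$, grid density 20).  The order is derived at run time: the
   standard equiripple estimate, incremented until the realised transfer
   function meets the ripple spec on a 4096-point grid (typically 383
   taps at 256 Hz).  The filter is applied with group-delay correction;
   the $(T-1)/2$ samples at each end are flagged invalid (the head/tail
   transients of high-order equiripple kernels).  The Hilbert transform
   (frequency-domain method) then gives instantaneous phase and envelope.
   The stimulus (photodiode) trace passes through the *same* filter and
   Hilbert chain, so both signals see the same (zero) distortion.
7. **PLV / PLS**: the phase-locking value is the modulus of the
   trial-averaged unit phasor of the channel-minus-stimulus phase
   difference.  Significance comes from surrogates that pair the target
   condition's trial phases with trial-shuffled stimulus phases from a
   randomly chosen *other* condition; PLS is the fraction of surrogate
   PLVs above the observed one.  200 surrogates give a PLS resolution of
   0.005 against the 0.05 threshold.  The threshold is applied
   inclusively (PLS ≤ 0.05); with 200 surrogates the difference from a
   strict inequality arises only when PLS lands exactly on 0.05.
8. **Locking delays and source**: per channel, the first post-onset valid
   sample with PLV > 0.5 and significant PLS, in seconds; the source is
   the channel locking first in the plurality of conditions (ties: lower
   mean delay, then posterior-first order).  The analysis convention pins
   the source to Pz by default (`source_override`), mirroring standard
   practice when one channel is known to lead; setting the override to
   `NULL` uses the data-driven winner.
9. **Velocity**: per-channel lags are circular means of the
   source-minus-channel phase difference over windows of 5 stimulation
   cycles; the gradient fit is ordinary least squares of unwrapped lag on
   distance over the electrode band O1, O2, Oz, PO3, PO4, P3, Pz, P4,
   CP1, CP2, Cz, FC1, FC2, Fz, with Pearson r and its two-sided p.

### Unwrapping

Wrapped lags alias as soon as the true gradient exceeds π between
neighbouring (in distance) electrodes — at λ ≈ 22 cm the montage's far
electrodes carry true lags above 4 rad, so unwrapping is not optional.
The package unwraps along electrodes sorted by increasing distance, but
*predictively*: each lag is wrapped against the value extrapolated from
the line fitted to the electrodes already unwrapped (proportional
extrapolation through the source's exact zero while fewer than three
points are available).  Naive nearest-neighbour chaining turned out to be
the single largest failure mode at realistic noise: one far, low-SNR
electrode occasionally wraps by 2π and drags every later electrode with
it, and because overflow is only possible in one direction the resulting
slope error is systematically biased.  Predictive unwrapping removes both
the cascades and the bias; the test suite includes an artificial
λ = 10 cm case where naive wrapped fitting demonstrably fails.

### Pooling the lag windows

The source-relative phase difference is constant throughout the
steady-state stimulation period, and the analysis computes it every
250 ms.  `estimate_velocity()` therefore pools the per-window lag phasors
over window centres 0.25–1.75 s before fitting.  The reason is
statistical: the ±1 Hz narrowband leaves roughly one independent noise
sample per 5-cycle window, so a single-window fit from a 10-trial session
has ~50% relative slope noise; a single-subject session simply does not
carry enough data for a stable one-window estimate (group studies pool
dozens of subjects at this point).  Pooling the seven steady-state
windows brings per-condition velocity recovery to within a few percent.
A single-window (`window_centers = 0.25`) estimate remains available and
is what the per-condition correlation r ≈ 0.85–0.9 refers to; pooled fits
reach r ≈ 0.99.

## The synthetic generator

`simulate_recording()` realises the simplest generative model consistent
with the estimator's assumptions: a sinusoid at the stimulation frequency
on every channel with the phase lag $2\pi f d/v(f)$, amplitude
$A\,e^{-d/s}$, and an onset envelope (latency, then a linear ramp) whose
start itself travels at $v(f)$; plus channel-independent 1/f background
noise (synthesized in the frequency domain over 0.5–128 Hz), common-phase
line interference at 50 Hz, and optionally a spatially smooth shared
noise component (Gaussian kernel over scalp distance) mimicking
volume-conducted ongoing activity.  All randomness flows from one integer
seed through a fixed draw order (trial order, ISIs, line phase, noise
channel by channel), so identical seeds give bitwise-identical sessions.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| sampling rate | 2048 Hz | active-electrode acquisition standard |
| frequencies | 40–60 Hz, step 2, no 50 | gamma band, line frequency excluded |
| trials × duration | 10 × 2 s, ISI U(3, 6) s | standard SSVEP session design |
| v(f) | 8.6 + 0.24·(f − 40) m/s | gamma-band scalp wave velocities |
| source | Pz | earliest-locking channel in this paradigm |
| amplitude | 4 µV at source | upper range of gamma SSVEP amplitudes |
| amplitude decay | 10 cm | posterior-dominant topography with measurable frontal response |
| onset latency + ramp | 0.1 + 0.15 s | response saturating by ~250 ms |
| background | 1/f, 15 µV rms | typical broadband ongoing EEG |
| line | 10 µV rms at 50 Hz | realistic mains pickup |

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: biophysical volume conduction (dipoles, lead
fields), ocular and muscle artifacts, harmonic SSVEP content (available
but off by default; the analysis is narrowband per condition), cortical
folding (an optional multiplicative reporting factor, default off), and
any perceptual nonlinearity near the flicker-fusion threshold.  Two
consequences are documented here deliberately:

- **Ground-truth recovery bypasses the Laplacian.**  The generator writes
  the wave's phases directly onto the channels; there is no
  volume-conducted blur for the Laplacian to undo.  Applying a spatial
  second derivative to an exponentially decaying wavefield multiplies the
  complex field by a distance-dependent factor (the curvature term of the
  Laplacian on a sphere), rotating phases non-uniformly — measured ~22%
  velocity bias on noise-free synthetic data.  Recovery experiments
  therefore run `spatial_filter = "none"`, while the default pipeline for
  topographic outputs keeps the Laplacian, whose purpose is real-data
  denoising, not synthetic-data fidelity.
- **The reference-artifact contrast is out of model.**  The classic
  observation that common-average-referenced data show spurious
  stimulus-free phase gradients which the Laplacian eliminates depends on
  volume conduction; with the generator's shared-noise component the
  testable mechanism is that distant-channel correlation survives CAR but
  is suppressed by the Laplacian, and that is what the suite asserts.

## Numerical and statistical notes

- The PLV is exactly 1 for a single trial; the implementation requires
  N ≥ 2.  For N uniform phases the expected PLV is
  $\sqrt{\pi}/2\cdot N^{-1/2}$ (≈ 0.089 at N = 100), verified by
  Monte Carlo.
- The surrogate PLS at threshold α = 0.05 with 200 surrogates has null
  rejection probability 11/201 ≈ 0.0547 under exchangeability (inclusive
  threshold); the calibration suite checks the empirical rate to within
  Monte-Carlo error over 500 null replicates.
- The ERS percent-change statistic carries a small positive bias on pure
  noise (the pooled baseline power sits in a denominator, and
  E[1/P] > 1/E[P]): about +7% at 10 trials.  This is a property of the
  ratio estimator, not of the implementation; the noise-only test checks
  for the absence of stimulus-locked or posterior-weighted structure
  rather than an exact zero mean.
- Epoch windows are resolved to sample indices by rounding; degenerate
  windows (zero length), windows touching filter-invalid samples, zero
  baseline power, and rank-deficient gradient fits all raise explicit
  errors naming the offending quantity.
- Filter designs are memoised per (centre, rate, spec) since the same
  design recurs for every seed and condition.

## Problem sizes

The recovery experiments simulate 20 full sessions (10 conditions × 10
trials at 2048 Hz, ~11 minutes of signal each) and take a few minutes in
total; the PLS calibration uses 500 null replicates × 200 surrogates; the
oracle comparisons (haversine vs arccos, FFT Hilbert vs kernel
convolution, realised filter response vs ripple spec) run in seconds.
Unit tests use miniature sessions (1–3 conditions, 1–10 trials) generated
in code.

## Known limitations

Single-recording scope (multi-subject studies are represented by
multi-seed batches aggregated at report level); no ICA ocular-artifact
stage (synthetic data are artifact-free; the component-selection
heuristic — the component with the highest front–back spatial difference —
is documented but not implemented); no 2-D vector phase-gradient or
wave-direction maps; locking delays at single-session trial counts are
intrinsically jittery, which is why the source is pinned to Pz by default
rather than re-derived per run.
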
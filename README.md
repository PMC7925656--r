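# ssvepwave

Analysis of the generation and scalp propagation of high-frequency
steady-state visual evoked potentials (SSVEPs) from multichannel EEG.

When a subject views a light flickering at a frequency *f* in the gamma
band (40–60 Hz), the EEG carries an oscillatory response at *f* that is
time- and phase-locked to the stimulus.  Across the scalp this response
shows a progressive phase shift away from a parieto-occipital source — the
signature of a traveling wave.  This package implements the full analysis
chain that turns raw multichannel recordings into quantitative propagation
estimates, together with a synthetic traveling-wave EEG generator with
known ground truth, so every stage is testable end to end:

- **Montage geometry** — electrodes on a spherical head model (radius
  *r* = 9 cm); great-circle distances by the haversine formula
  Δδ = 2·r·arcsin √hav(α).
- **Synthetic sessions** — square-wave photic stimulation (40–60 Hz in
  2 Hz steps excluding the 50 Hz line frequency, 10 trials per condition,
  2 s stimulation, 3–6 s inter-stimulus intervals) driving a scalp wave
  that propagates isotropically from a source channel at a
  frequency-dependent velocity v(f), with exponential amplitude decay,
  superposed on 1/f background noise and line interference.
- **Preprocessing** — zero-phase IIR line notch, anti-aliased decimation
  2048 → 256 Hz, spherical-spline surface Laplacian (reference-free
  spatial sharpening), stimulus-locked epochs from −1 s to +3 s.
- **ERS maps** — Hanning-window STFT (126-sample window, fractional
  4.5-sample hop, 200 windows per 4 s epoch) and the percent power change
  per 250 ms window against the pre-stimulus baseline.
- **Phase synchrony** — per-condition Parks–McClellan equiripple bandpass
  (pass ±1 Hz, stop ±3 Hz, ripples 0.058 / 1e-4) with group-delay
  correction, Hilbert instantaneous phase, the phase-locking value
  PLV(t) = |1/N Σₙ exp(i Δφₙ(t))| against the photodiode trace, a
  trial-shuffled surrogate significance test (PLS), locking delays
  (first sample with PLV > 0.5 and PLS ≤ 0.05), and propagation-source
  selection.
- **Propagation** — windowed source-relative phase lags (circular means
  over 5 stimulation cycles), a first-order polynomial fit of unwrapped
  lag against great-circle distance, the phase velocity
  v = 2πf·Δδ/Δφ (equivalently 2πf/slope), the wavelength λ = 100·v/f cm,
  and the velocity-versus-frequency regression.

## Worked example

Simulate a short session (three conditions, ten trials each, realistic
noise), preprocess it and estimate the propagation:

```r
library(ssvepwave)
cfg <- default_config(seed = 42)
cfg$protocol$frequencies <- c(40, 48, 60)
cfg$analysis$run_ers <- FALSE
cfg$analysis$run_pls <- FALSE
cfg$preprocess$spatial_filter <- "none"
res <- run_pipeline(cfg)
print(res)
```

```
<ssvep_run>
  events: 30 | source used: Pz
<ssvep_velocity> source Pz, window(s) at 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75 s
  freq slope_rad_per_cm intercept      r         p velocity wavelength
1   40           0.2745   0.06055 0.9962 4.290e-14    9.157      22.89
2   48           0.2884  -0.01839 0.9823 4.232e-10   10.458      21.79
3   60           0.2808   0.09468 0.9917 4.538e-12   13.427      22.38
trend: 0.350 + 0.216 * f m/s (r = 0.994, p = 0.068)
```

Each row is one stimulation condition: the spatial phase gradient (rad/cm)
fitted over the parieto-occipital-to-frontal electrode band, its Pearson
correlation and p value, and the derived phase velocity (m/s) and scalp
wavelength (cm).  The generator's ground truth here is
v(f) = 8.6 + 0.24·(f − 40) m/s from channel Pz; the recovered velocities
(9.16, 10.46, 13.43 m/s) sit within a few percent of it
(truth: 8.60, 10.52, 13.40), and the trend line recovers the
0.24 (m/s)/Hz frequency dependence from just three conditions within its
confidence range.

A command-line front end for the same pipeline lives at
`inst/cli/ssvepwave.R`
(`Rscript inst/cli/ssvepwave.R all --config cfg.yaml --out results/`).

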
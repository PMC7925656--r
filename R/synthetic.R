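#' Stimulation protocol description
#'
#' Defaults follow a gamma-band photic stimulation protocol: square-wave
#' flicker at 40-60 Hz in 2 Hz steps excluding the 50 Hz line frequency,
#' 10 trials per condition, 2 s stimulation separated by inter-stimulus
#' intervals drawn uniformly from 3-6 s, 100% modulation depth and 50%
#' duty cycle.
#'
#' @param frequencies stimulation frequencies in Hz.
#' @param trials_per_condition trials per frequency.
#' @param stim_duration stimulation duration, s.
#' @param isi_range lower/upper bound of the uniform inter-stimulus
#'   interval, s.
#' @param duty_cycle on-fraction of the square wave, in (0, 1].
#' @param modulation_depth stimulus modulation depth, fraction.
#' @return an object of class `ssvep_protocol`.
#' @export
stim_protocol <- function(frequencies = c(40, 42, 44, 46, 48, 52, 54, 56,
                                          58, 60),
                          trials_per_condition = 10,
                          stim_duration = 2,
                          isi_range = c(3, 6),
                          duty_cycle = 0.5,
                          modulation_depth = 1.0) {
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (duty_cycle <= 0 || duty_cycle > 1) stop("duty_cycle must be in (0, 1]")
  if (isi_range[1] > isi_range[2]) stop("isi_range must be non-decreasing")
  if (trials_per_condition < 1) stop("trials_per_condition must be >= 1")
  structure(list(frequencies = frequencies,
                 trials_per_condition = trials_per_condition,
                 stim_duration = stim_duration,
                 isi_range = isi_range,
                 duty_cycle = duty_cycle,
                 modulation_depth = modulation_depth),
            class = "ssvep_protocol")
}

#' Traveling-wave propagation model for the synthetic SSVEP
#'
#' The synthetic SSVEP spreads isotropically from a single scalp source.
#' A channel at great-circle distance d (cm) from the source carries, during
#' stimulation, a sinusoid at the stimulation frequency f whose phase lags
#' the source by `2*pi*f*d / v(f)` (v in cm/s), whose amplitude is
#' `amplitude * exp(-d / amplitude_decay)`, and whose onset envelope starts
#' `onset_latency + d / v(f)` after stimulus onset and ramps linearly to 1
#' over `onset_ramp` seconds.  The default velocity law is linear in
#' frequency, `v(f) = v0 + v_slope * (f - f_ref)` m/s.
#'
#' @param source source channel label.
#' @param v0 phase velocity at `f_ref`, m/s.
#' @param v_slope increase in velocity per Hz, (m/s)/Hz.
#' @param f_ref reference frequency for the linear law, Hz.
#' @param velocity_fun optional function(f) -> m/s overriding the linear law.
#' @param amplitude source SSVEP amplitude, uV.
#' @param amplitude_decay spatial scale of exponential amplitude falloff, cm.
#' @param onset_latency response latency at the source, s.
#' @param onset_ramp linear onset ramp duration, s.
#' @param harmonic_weights relative amplitudes of the fundamental and
#'   optional harmonics (first element = fundamental).
#' @return an object of class `ssvep_wave_model`.
#' @export
wave_model <- function(source = "Pz", v0 = 8.6, v_slope = 0.24, f_ref = 40,
                       velocity_fun = NULL, amplitude = 4,
                       amplitude_decay = 10, onset_latency = 0.1,
                       onset_ramp = 0.15, harmonic_weights = 1) {
  if (onset_latency < 0 || onset_ramp < 0)
    stop("onset_latency and onset_ramp must be >= 0")
  if (amplitude < 0 || amplitude_decay <= 0)
    stop("amplitude must be >= 0 and amplitude_decay > 0")
  structure(list(source = source, v0 = v0, v_slope = v_slope, f_ref = f_ref,
                 velocity_fun = velocity_fun, amplitude = amplitude,
                 amplitude_decay = amplitude_decay,
                 onset_latency = onset_latency, onset_ramp = onset_ramp,
                 harmonic_weights = harmonic_weights),
            class = "ssvep_wave_model")
}

#' Ground-truth phase velocity of a wave model
#' @param wave a [wave_model()].
#' @param f frequency in Hz (vectorized).
#' @return velocity in m/s.
#' @export
model_velocity <- function(wave, f) {
  v <- if (is.function(wave$velocity_fun)) wave$velocity_fun(f)
       else wave$v0 + wave$v_slope * (f - wave$f_ref)
  if (any(v <= 0)) stop("wave model velocity must be positive")
  v
}

#' Additive noise model for the synthetic EEG
#'
#' Background activity is 1/f^a ("pink") noise synthesized independently per
#' channel in the 0.5-128 Hz band, plus a common-phase sinusoidal line
#' interference component on every channel.
#'
#' @param background_exponent spectral exponent a of the 1/f^a background.
#' @param background_rms per-channel RMS of the background, uV.
#' @param line_freq line interference frequency, Hz.
#' @param line_rms RMS of the line component, uV.
#' @param spatial_scale optional spatial correlation scale of the
#'   background, cm; 0 (default) gives channel-independent noise, larger
#'   values mix the channel noises with a Gaussian kernel
#'   `exp(-(d/scale)^2/2)` over great-circle distance to mimic
#'   volume-conducted common activity.
#' @return an object of class `ssvep_noise_model`.
#' @export
noise_model <- function(background_exponent = 1, background_rms = 15,
                        line_freq = 50, line_rms = 10, spatial_scale = 0) {
  if (background_rms < 0 || line_rms < 0) stop("rms values must be >= 0")
  if (spatial_scale < 0) stop("spatial_scale must be >= 0")
  structure(list(background_exponent = background_exponent,
                 background_rms = background_rms,
                 line_freq = line_freq, line_rms = line_rms,
                 spatial_scale = spatial_scale),
            class = "ssvep_noise_model")
}

#' Square-wave photic stimulus waveform
#'
#' @param f flicker frequency, Hz; must be below `rate/2`.
#' @param duration duration, s.
#' @param rate sampling rate, Hz.
#' @param duty on-fraction in (0, 1].
#' @return numeric 0/1 vector of length `round(duration * rate)`.
#' @export
make_stimulus_signal <- function(f, duration, rate, duty = 0.5) {
  if (f >= rate / 2)
    stop(sprintf("invalid frequency: %g Hz not below Nyquist %g Hz",
                 f, rate / 2))
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  as.numeric((tt * f) %% 1 < duty)
}

#' Construct a continuous multichannel recording
#'
#' @param data numeric matrix, samples x channels, uV.
#' @param rate sampling rate, Hz.
#' @param channel_names channel labels (length = ncol(data)).
#' @param stim stimulus (photodiode-equivalent) trace, length = nrow(data).
#' @param events data frame with columns `onset` (sample index, 1-based) and
#'   `freq` (condition frequency, Hz).
#' @param ground_truth optional list describing the generating model.
#' @return an object of class `ssvep_recording`.
#' @export
recording <- function(data, rate, channel_names, stim,
                      events = data.frame(onset = integer(), freq = numeric()),
                      ground_truth = NULL) {
  data <- as.matrix(data)
  if (length(channel_names) != ncol(data))
    stop("channel_names length must match ncol(data)")
  if (length(stim) != nrow(data))
    stop("stim channel length must equal the number of samples")
  if (nrow(events) &&
      any(events$onset < 1 | events$onset > nrow(data)))
    stop("event onsets must lie within the recording")
  colnames(data) <- channel_names
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 stim = as.numeric(stim), events = events,
                 ground_truth = ground_truth),
            class = "ssvep_recording")
}

#' @export
print.ssvep_recording <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_recording> %d channels x %d samples @ %g Hz",
                     " (%.1f s), %d events\n"),
              ncol(x$data), nrow(x$data), x$rate,
              nrow(x$data) / x$rate, nrow(x$events)))
  invisible(x)
}

# 1/f^a band-limited noise, two independent real channels per complex ifft
.pink_noise_pair <- function(n, rate, exponent, f_lo = 0.5, f_hi = 128) {
  m <- 2^15 * ceiling(n / 2^15)        # friendly FFT length
  f <- (seq_len(m) - 1) * rate / m
  keep <- which(f >= f_lo & f <= min(f_hi, rate / 2))
  spec <- complex(real = rep(0, m), imaginary = rep(0, m))
  w <- f[keep]^(-exponent / 2)
  spec[keep] <- complex(real = rnorm(length(keep)),
                        imaginary = rnorm(length(keep))) * w
  z <- fft(spec, inverse = TRUE)[seq_len(n)]
  list(Re(z), Im(z))
}

#' Simulate a continuous traveling-wave SSVEP recording
#'
#' Generates a full stimulation session: randomized trial order, uniform
#' inter-stimulus intervals, a photodiode-equivalent square-wave stimulus
#' trace, and on every EEG channel the traveling-wave SSVEP of
#' [wave_model()] superposed on the background and line noise of
#' [noise_model()].  All randomness flows from `seed` through a single
#' stream with a fixed draw order (trial order, ISIs, line phase, then
#' background noise channel by channel), so equal seeds give bitwise equal
#' recordings.
#'
#' @param protocol a [stim_protocol()].
#' @param wave a [wave_model()]; its source must be a montage channel.
#' @param noise a [noise_model()].
#' @param montage a [montage()].
#' @param rate sampling rate, Hz (default 2048).
#' @param seed integer seed.
#' @return an [recording()] whose `ground_truth` holds the generator
#'   parameters.
#' @export
simulate_recording <- function(protocol = stim_protocol(),
                               wave = wave_model(),
                               noise = noise_model(),
                               montage = default_montage(),
                               rate = 2048, seed = 1) {
  stopifnot(inherits(protocol, "ssvep_protocol"),
            inherits(wave, "ssvep_wave_model"),
            inherits(noise, "ssvep_noise_model"),
            inherits(montage, "ssvep_montage"))
  if (!(wave$source %in% montage$name))
    stop("unknown source channel: ", wave$source)
  if (any(protocol$frequencies >= rate / 2))
    stop("stimulation frequency at or above Nyquist")
  set.seed(as.integer(seed))
  freqs <- protocol$frequencies
  ntr <- protocol$trials_per_condition
  n_trials <- length(freqs) * ntr
  cond_seq <- rep(freqs, each = ntr)[sample.int(n_trials)] # draw 1: order
  isis <- runif(n_trials, protocol$isi_range[1],
                protocol$isi_range[2])                    # draw 2: ISIs
  stim_s <- round(protocol$stim_duration * rate)
  onsets <- integer(n_trials)
  t_cursor <- 0
  for (i in seq_len(n_trials)) {
    t_cursor <- t_cursor + isis[i]
    onsets[i] <- floor(t_cursor * rate) + 1L
    t_cursor <- t_cursor + protocol$stim_duration
  }
  n <- onsets[n_trials] + stim_s + round(2 * rate)        # 2 s tail pad
  nch <- nrow(montage)
  dist <- channel_distances(montage, wave$source)
  X <- matrix(0, n, nch)
  line_phi <- runif(1, 0, 2 * pi)                         # draw 3: line phase
  if (noise$line_rms > 0) {
    tt <- (seq_len(n) - 1) / rate
    line <- noise$line_rms * sqrt(2) *
      sin(2 * pi * noise$line_freq * tt + line_phi)
    X <- X + line                                         # common to channels
  }
  if (noise$background_rms > 0) {                         # draw 4: background
    ci <- 1L
    while (ci <= nch) {
      pair <- .pink_noise_pair(n, rate, noise$background_exponent)
      X[, ci] <- X[, ci] +
        pair[[1]] * (noise$background_rms / sd(pair[[1]]))
      if (ci + 1L <= nch)
        X[, ci + 1L] <- X[, ci + 1L] +
          pair[[2]] * (noise$background_rms / sd(pair[[2]]))
      ci <- ci + 2L
    }
    if (noise$spatial_scale > 0) {
      # add a spatially smooth shared component (independent generators
      # mixed with a Gaussian kernel over scalp distance) on top of the
      # channel-local background, mimicking volume-conducted activity;
      # the shared part carries the same rms as the local part
      r <- attr(montage, "radius")
      xyz <- .montage_xyz(montage)
      ang <- matrix(acos(pmin(1, pmax(-1, as.vector(tcrossprod(xyz))))),
                    nch, nch)
      K <- exp(-(ang * r / noise$spatial_scale)^2 / 2)
      K <- K / rowSums(K)
      S <- matrix(0, n, nch)
      ci <- 1L
      while (ci <= nch) {
        pair <- .pink_noise_pair(n, rate, noise$background_exponent)
        S[, ci] <- pair[[1]] / sd(pair[[1]])
        if (ci + 1L <= nch) S[, ci + 1L] <- pair[[2]] / sd(pair[[2]])
        ci <- ci + 2L
      }
      S <- S %*% t(K)
      X <- X + sweep(S, 2, apply(S, 2, sd), "/") * noise$background_rms
    }
  }
  # traveling-wave SSVEP
  v_cm <- 100 * model_velocity(wave, cond_seq)            # per trial, cm/s
  tt_stim <- (seq_len(stim_s) - 1) / rate
  hw <- wave$harmonic_weights
  for (i in seq_len(n_trials)) {
    f <- cond_seq[i]
    idx <- onsets[i]:(onsets[i] + stim_s - 1L)
    for (c in seq_len(nch)) {
      d <- dist[c]
      amp <- wave$amplitude * protocol$modulation_depth *
        exp(-d / wave$amplitude_decay)
      if (amp < 1e-12) next
      arrival <- wave$onset_latency + d / v_cm[i]
      env <- if (wave$onset_ramp > 0)
        pmin(1, pmax(0, (tt_stim - arrival) / wave$onset_ramp))
      else as.numeric(tt_stim >= arrival)
      lag <- 2 * pi * f * d / v_cm[i]
      s <- 0
      for (k in seq_along(hw))
        s <- s + hw[k] * sin(k * (2 * pi * f * tt_stim - lag))
      X[idx, c] <- X[idx, c] + amp * env * s
    }
  }
  stim <- numeric(n)
  for (i in seq_len(n_trials)) {
    idx <- onsets[i]:(onsets[i] + stim_s - 1L)
    stim[idx] <- make_stimulus_signal(cond_seq[i], protocol$stim_duration,
                                      rate, protocol$duty_cycle)
  }
  recording(X, rate, montage$name, stim,
            events = data.frame(onset = onsets, freq = cond_seq),
            ground_truth = list(protocol = protocol, wave = wave,
                                noise = noise, seed = as.integer(seed),
                                isi = isis))
}

#' Full visual angle subtended by a stimulus panel
#' @param size_cm panel extent, cm.
#' @param distance_cm viewing distance, cm.
#' @return full visual angle in degrees.
#' @export
visual_angle <- function(size_cm, distance_cm) {
  2 * atan(size_cm / (2 * distance_cm)) * 180 / pi
}

#' Expected SNR gain from trial averaging
#' @param n_trials number of averaged trials.
#' @return amplitude SNR improvement factor, `sqrt(n_trials)`.
#' @export
snr_gain <- function(n_trials) sqrt(n_trials)

#' Write / read a recording in the native lossless container
#'
#' The native container is an RDS serialization of the recording's fields
#' (data, rate, names, stimulus trace, events, ground truth); the roundtrip
#' is lossless.  For interchange with other EEG software see [write_edf()].
#'
#' @param rec an [recording()].
#' @param path file path.
#' @return `read_recording` returns the [recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ssvep_recording"))
  saveRDS(unclass(rec), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("malformed recording file ", path,
                                           ": ", conditionMessage(e)))
  need <- c("data", "rate", "channel_names", "stim", "events")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop("malformed recording file ", path, ": missing fields")
  recording(obj$data, obj$rate, obj$channel_names, obj$stim, obj$events,
            obj$ground_truth)
}
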
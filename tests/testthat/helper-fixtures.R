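# Shared fixtures, generated in code.

# small noise-free session: few conditions/trials, fast to simulate
tiny_session <- function(freqs = c(40, 44, 60), trials = 3, seed = 7,
                         noise = noise_model(background_rms = 0,
                                             line_rms = 0),
                         wave = wave_model(), rate = 2048) {
  simulate_recording(stim_protocol(frequencies = freqs,
                                   trials_per_condition = trials),
                     wave, noise, default_montage(), rate = rate,
                     seed = seed)
}

# recording holding pure sinusoids on every channel (for filter probes)
sinusoid_recording <- function(f, rate = 2048, dur = 4, nchan = 2,
                               amp = 1, phase = 0) {
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  x <- amp * sin(2 * pi * f * tt + phase)
  recording(matrix(rep(x, nchan), ncol = nchan),
            rate, paste0("ch", seq_len(nchan)), numeric(n))
}

rms <- function(x) sqrt(mean(x^2))

wrap_pi_ref <- function(x) pi - (pi - x) %% (2 * pi)

# reference great-circle distance via the vector-angle (arccos) identity
arc_distance <- function(lat1, lon1, lat2, lon2, r = 9) {
  u <- c(cos(lat1) * sin(lon1), cos(lat1) * cos(lon1), sin(lat1))
  v <- c(cos(lat2) * sin(lon2), cos(lat2) * cos(lon2), sin(lat2))
  r * acos(min(1, max(-1, sum(u * v))))
}
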
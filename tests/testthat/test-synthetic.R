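test_that("stimulus square wave has the right duty cycle and spectrum", {
  s <- make_stimulus_signal(44, 2, 2048, duty = 0.5)
  expect_length(s, 4096)
  expect_true(all(s %in% c(0, 1)))
  expect_equal(mean(s), 0.5, tolerance = 1e-2)
  # strongest non-DC spectral component at the flicker frequency
  sp <- Mod(fft(s - mean(s)))[2:2048]
  expect_equal(which.max(sp), 44 * 2 + 1 - 1)   # bin spacing 0.5 Hz
  expect_equal(make_stimulus_signal(10, 1, 100, duty = 1),
               rep(1, 100))
  expect_error(make_stimulus_signal(1024, 1, 2048), "Nyquist")
})

test_that("simulation is bitwise deterministic in the seed", {
  pr <- stim_protocol(frequencies = c(40, 44), trials_per_condition = 2)
  r1 <- simulate_recording(pr, rate = 512, seed = 123)
  r2 <- simulate_recording(pr, rate = 512, seed = 123)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$stim, r2$stim)
  expect_identical(r1$events, r2$events)
  r3 <- simulate_recording(pr, rate = 512, seed = 124)
  expect_false(identical(r1$data, r3$data))
})

test_that("the default protocol produces 10 x 10 events", {
  rec <- simulate_recording(stim_protocol(),
                            noise = noise_model(background_rms = 0,
                                                line_rms = 0),
                            rate = 512, seed = 5)
  expect_equal(nrow(rec$events), 100)
  expect_equal(as.vector(table(rec$events$freq)), rep(10, 10))
  # every stimulation window lies inside the recording
  expect_true(all(rec$events$onset + 2 * 512 <= nrow(rec$data)))
})

test_that("noise-free channels carry the constructed phase lags", {
  rec <- tiny_session(freqs = 44, trials = 1, seed = 3)
  on <- rec$events$onset[1]
  idx <- (on + round(0.5 * 2048)):(on + round(1.9 * 2048))
  f <- 44; v <- model_velocity(wave_model(), f) * 100   # cm/s
  d <- channel_distances(default_montage(), "Pz")
  p1 <- instantaneous_phase(rec$data[idx, "CP1"])$phase
  p2 <- instantaneous_phase(rec$data[idx, "Fz"])$phase
  interior <- seq(1200, length(idx) - 1200) # clear of segment-edge Gibbs
  dphi <- phase_difference(p1[interior], p2[interior])
  expected <- wrap_pi_ref(2 * pi * f * (d["Fz"] - d["CP1"]) / v)
  expect_lt(max(abs(dphi - expected)), 1e-3)
})

test_that("inter-stimulus intervals are uniform on [3, 6] s", {
  isis <- unlist(lapply(1:20, function(s) {
    rec <- simulate_recording(
      stim_protocol(frequencies = 40, trials_per_condition = 20),
      noise = noise_model(background_rms = 0, line_rms = 0),
      rate = 256, seed = 2000 + s)
    rec$ground_truth$isi
  }))
  expect_gte(length(isis), 200)
  expect_true(all(isis >= 3 & isis <= 6))
  ks <- suppressWarnings(stats::ks.test(isis, "punif", 3, 6))
  expect_gt(ks$p.value, 0.01)
})

test_that("stimulation adds energy at the fundamental on near channels", {
  bandpow <- function(rec, idx_fun, ch) {
    sum(vapply(rec$events$onset, function(on) {
      x <- rec$data[idx_fun(on), ch]
      sp <- Mod(fft(x))^2
      fr <- (seq_along(x) - 1) * 512 / length(x)
      sum(sp[fr >= 43 & fr <= 45])
    }, numeric(1)))
  }
  stim_idx <- function(on) on:(on + 2 * 512 - 1)
  pre_idx <- function(on) (on - 2 * 512):(on - 1)
  d <- channel_distances(default_montage(), "Pz")
  # noise-free: every channel within 3 amplitude-decay scales gains energy
  rec0 <- simulate_recording(
    stim_protocol(frequencies = 44, trials_per_condition = 2),
    noise = noise_model(background_rms = 0, line_rms = 0),
    rate = 512, seed = 9)
  for (ch in names(d)[d <= 3 * wave_model()$amplitude_decay])
    expect_gt(bandpow(rec0, stim_idx, ch), bandpow(rec0, pre_idx, ch))
  # under the default ongoing noise the gain survives trial pooling on the
  # channels whose response sits clearly above the in-band noise
  rec <- simulate_recording(
    stim_protocol(frequencies = 44, trials_per_condition = 10),
    noise = noise_model(), rate = 512, seed = 9)
  for (ch in names(d)[d <= wave_model()$amplitude_decay])
    expect_gt(bandpow(rec, stim_idx, ch), bandpow(rec, pre_idx, ch))
})

test_that("the native container roundtrips losslessly", {
  rec <- tiny_session(freqs = 44, trials = 2, seed = 2)
  p <- withr::local_tempfile(fileext = ".rds")
  write_recording(rec, p)
  rec2 <- read_recording(p)
  expect_identical(rec2$data, rec$data)
  expect_identical(rec2$events, rec$events)
  expect_identical(rec2$rate, rec$rate)
  expect_error(read_recording(withr::local_tempfile(fileext = ".rds")),
               "not found")
})

test_that("EDF export roundtrips within the 16-bit quantization step", {
  rec <- tiny_session(freqs = 44, trials = 1, seed = 4)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  rec2 <- read_edf(p)
  expect_equal(rec2$rate, rec$rate)
  expect_equal(rec2$channel_names, rec$channel_names)
  n <- nrow(rec$data)
  for (ch in c("Pz", "Fz")) {
    step <- diff(range(rec$data[, ch])) / 65535
    expect_lt(max(abs(rec2$data[seq_len(n), ch] - rec$data[, ch])),
              step)
  }
  expect_equal(rec2$events, rec$events)
})

test_that("a truncated EDF file raises an explicit error", {
  rec <- tiny_session(freqs = 44, trials = 1, seed = 4, rate = 512)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  full <- readBin(p, "raw", file.info(p)$size)
  writeBin(full[seq_len(length(full) - 4096)], p)
  expect_error(read_edf(p), "truncated")
})

test_that("recording invariants are enforced", {
  expect_error(recording(matrix(0, 10, 2), 100, c("a", "b"), numeric(9)),
               "stim channel length")
  expect_error(recording(matrix(0, 10, 2), 100, c("a", "b"), numeric(10),
                         events = data.frame(onset = 11, freq = 40)),
               "within the recording")
  expect_error(simulate_recording(stim_protocol(frequencies = 300),
                                  rate = 512),
               "Nyquist")
  expect_error(simulate_recording(wave = wave_model(source = "XX"),
                                  rate = 512),
               "unknown source")
})
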
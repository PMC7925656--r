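# transfer function evaluated directly from the coefficients (independent
# of the package's internal response evaluation)
freqz_ref <- function(h, f, rate) {
  vapply(f, function(ff)
    abs(sum(h * exp(-2i * pi * ff * (seq_along(h) - 1) / rate))), 1)
}

test_that("the equiripple bandpass meets its printed specification", {
  bp <- design_bandpass(44, 256)
  expect_equal(bp$taps %% 2, 1)                       # type-I linear phase
  expect_equal(bp$coef, rev(bp$coef))                 # symmetric
  expect_equal(bp$group_delay, (bp$taps - 1) / 2)
  f <- seq(0, 128, length.out = 4096)
  H <- freqz_ref(bp$coef, f, 256)
  pass <- f >= 43 & f <= 45
  stop <- f <= 41 | f >= 47
  expect_gte(min(H[pass]), 1 - 0.058)
  expect_lte(max(abs(H[pass] - 1)), 0.058)
  expect_lte(max(H[stop]), 1e-4 * (1 + 1e-6))
  expect_error(design_bandpass(60, 122), "design error")
})

test_that("zero-delay filtering leaves a passband probe untouched", {
  bp <- design_bandpass(44, 256)
  tt <- (0:4095) / 256
  x <- sin(2 * pi * 44 * tt)
  out <- apply_zero_delay(x, bp)
  expect_equal(sum(!out$valid), bp$taps - 1)
  ph_in <- instantaneous_phase(x)$phase
  ph_out <- instantaneous_phase(out$x)$phase
  interior <- which(out$valid)[seq(100, sum(out$valid) - 100)]
  expect_lt(max(abs(wrap_pi_ref(ph_out[interior] - ph_in[interior]))),
            0.01)
  # cross-correlation peaks at zero lag
  cc <- ccf(out$x[out$valid], x[out$valid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_equal(apply_zero_delay(numeric(4096), bp)$x, numeric(4096))
  expect_error(apply_zero_delay(numeric(100), bp), "shorter")
})

test_that("filtered white noise is confined to the design band", {
  bp <- design_bandpass(44, 256)
  set.seed(10)
  x <- rnorm(2^14)
  out <- apply_zero_delay(x, bp)
  y <- out$x[out$valid]
  sp <- Mod(fft(y))^2
  fr <- (seq_along(y) - 1) * 256 / length(y)
  inband <- (fr >= 41 & fr <= 47) | (fr >= 256 - 47 & fr <= 256 - 41)
  expect_gte(sum(sp[inband]) / sum(sp), 0.999)
})

test_that("Hilbert phase and envelope match the analytic signal", {
  tt <- (0:2047) / 256
  x <- 3 * cos(2 * pi * 44 * tt)
  hp <- instantaneous_phase(x)
  interior <- 100:1948
  expect_lt(max(abs(wrap_pi_ref(hp$phase[interior] -
                                  wrap_pi_ref(2 * pi * 44 * tt[interior])))),
            0.01)
  expect_equal(hp$phase[1], 0, tolerance = 1e-2)
  expect_lt(max(abs(hp$amplitude[interior] - 3)) / 3, 0.01)
  z <- instantaneous_phase(numeric(512))
  expect_true(z$undefined)
  expect_false(any(is.nan(z$phase)))
})

test_that("frequency-domain Hilbert agrees with kernel convolution", {
  # truncated ideal discrete Hilbert kernel h[n] = 2/(pi n), n odd
  tt <- (0:2047) / 256
  x <- cos(2 * pi * 44 * tt) + 0.3 * cos(2 * pi * 46 * tt + 1)
  N <- 401
  off <- seq(-(N - 1) / 2, (N - 1) / 2)
  k <- ifelse(off %% 2 == 0, 0, 2 / (pi * off))
  xh <- vapply(seq_along(x), function(i) {
    j <- i - off
    ok <- j >= 1 & j <= length(x)
    sum(k[ok] * x[j[ok]])
  }, numeric(1))
  ph_ref <- atan2(xh, x)
  ph <- instantaneous_phase(x)$phase
  interior <- 300:1748
  expect_lt(max(abs(wrap_pi_ref(ph[interior] - ph_ref[interior]))), 0.01)
})

test_that("phase differences wrap to (-pi, pi]", {
  expect_equal(phase_difference(1.2, 1.2), 0)
  expect_equal(phase_difference(3 * pi / 2, 0), -pi / 2)
  expect_equal(phase_difference(pi, 0), pi)           # boundary -> +pi
  expect_equal(phase_difference(-pi / 2, pi / 2), pi) # ditto
  expect_error(phase_difference(matrix(0, 2, 2), matrix(0, 2, 3)),
               "identical shape")
})

test_that("PLV obeys its algebra and the Rayleigh small-sample mean", {
  expect_equal(plv(matrix(0.7, 5, 3)), rep(1, 3))
  expect_equal(plv(matrix(c(0, pi, 0, pi), 4, 1)), 0)
  expect_error(plv(matrix(0, 1, 4)), "at least 2 trials")
  set.seed(11)
  dphi <- matrix(runif(100 * 1e4, -pi, pi), 100)
  v <- plv(dphi)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(mean(v), sqrt(pi) / 2 / sqrt(100), tolerance = 0.02)
  # invariance to a common constant phase across trials
  expect_equal(plv(dphi + 1.234), v, tolerance = 1e-12)
})

fake_phase <- function(phase_arr, stim_phase, freq = 44, rate = 256) {
  S <- dim(phase_arr)[3]
  structure(list(phase = phase_arr, amplitude = abs(phase_arr) * 0 + 1,
                 stim_phase = stim_phase, valid = rep(TRUE, S),
                 t = (seq_len(S) - 1) / rate, rate = rate, freq = freq,
                 channel_names = dimnames(phase_arr)[[2]]),
            class = "ssvep_phase")
}

test_that("PLS is 0 for perfect locking and validates preconditions", {
  set.seed(12)
  S <- 8; Tn <- 10
  stim <- matrix(runif(Tn * S, -pi, pi), Tn)
  target <- fake_phase(array(stim, c(Tn, 1, S),
                             dimnames = list(NULL, "Pz", NULL)), stim)
  other <- fake_phase(array(runif(Tn * S, -pi, pi), c(Tn, 1, S),
                            dimnames = list(NULL, "Pz", NULL)),
                      matrix(runif(Tn * S, -pi, pi), Tn), freq = 56)
  res <- pls_surrogate(target, list(other), n_surrogates = 50, seed = 1)
  expect_equal(max(res$pls), 0)
  expect_equal(unname(res$plv[1, ]), rep(1, S))
  expect_equal(res$plv, stimulus_plv(target))
  expect_error(pls_surrogate(target, list(), 50), "no other condition")
  expect_error(pls_surrogate(target, list(other), 0), "at least 19")
})

test_that("PLS is roughly uniform when target and stimulus are unrelated", {
  set.seed(13)
  Tn <- 10
  pls1 <- vapply(1:300, function(i) {
    stim <- matrix(runif(Tn, -pi, pi), Tn)
    target <- fake_phase(array(runif(Tn, -pi, pi), c(Tn, 1, 1),
                               dimnames = list(NULL, "Pz", NULL)), stim)
    other <- fake_phase(array(0, c(Tn, 1, 1),
                              dimnames = list(NULL, "Pz", NULL)),
                        matrix(runif(Tn, -pi, pi), Tn), freq = 56)
    pls_surrogate(target, list(other), n_surrogates = 40)$pls[1, 1]
  }, numeric(1))
  expect_equal(mean(pls1 <= 0.2), 0.2, tolerance = 0.08)
  expect_equal(mean(pls1), 0.5, tolerance = 0.06)
})

fake_plv <- function(plv_mat, pls_mat, rate = 256, t0 = -0.5) {
  S <- ncol(plv_mat)
  rownames(pls_mat) <- rownames(plv_mat)
  structure(list(plv = plv_mat, pls = pls_mat,
                 n_trials = 10, n_surrogates = 100,
                 valid = rep(TRUE, S),
                 t = (seq_len(S) - 1) / rate + t0, freq = 44,
                 channel_names = rownames(plv_mat)),
            class = "ssvep_plv")
}

test_that("locking delay is the first significant supra-threshold sample", {
  pv <- fake_plv(matrix(0.9, 2, 512, dimnames = list(c("Pz", "Fz"), NULL)),
                 matrix(0.01, 2, 512))
  d <- locking_delay(pv)
  expect_equal(unname(d), c(0, 0))                # first sample with t >= 0
  pv$pls["Fz", ] <- 1                             # never significant
  expect_equal(unname(is.na(locking_delay(pv))), c(FALSE, TRUE))
  pv$plv["Pz", ] <- c(rep(0.2, 200), rep(0.95, 312))
  pv$pls["Pz", ] <- 0.01
  expect_equal(unname(locking_delay(pv)["Pz"]), pv$t[201])
})

test_that("source selection uses plurality, then mean delay, then posterior order", {
  m <- default_montage()
  D <- matrix(0.5, 3, 3, dimnames = list(NULL, c("Pz", "Oz", "Cz")))
  D[1, "Pz"] <- 0.1; D[2, "Pz"] <- 0.1; D[3, "Oz"] <- 0.1
  expect_equal(select_source(D, m), "Pz")
  # tie in wins -> smaller mean delay
  D2 <- matrix(c(0.1, 0.5, 0.5, 0.1, 0.9, 0.9), 2,
               dimnames = list(NULL, c("Pz", "Cz", "Fz")))
  D2[, "Cz"] <- c(0.1, 0.1); D2[, "Pz"] <- c(0.1, 0.2); D2[, "Fz"] <- 1
  expect_equal(select_source(D2, m), "Cz")
  # full tie -> most posterior channel
  D3 <- matrix(0.3, 2, 3, dimnames = list(NULL, c("Fz", "Cz", "Oz")))
  expect_equal(select_source(D3, m), "Oz")
  expect_equal(select_source(D3, m, override = "Pz"), "Pz")
  expect_error(select_source(D3, m, override = "XX"), "unknown source")
  expect_error(select_source(matrix(NA_real_, 1, 2,
                                    dimnames = list(NULL, c("Pz", "Cz"))),
                             m),
               "no channel")
})

test_that("ground-truth source and arrival order are recovered", {
  # moderate background noise: enough to randomize pre-arrival phases (the
  # noise-free limit degenerates: zero signal has constant phase), low
  # enough for single-session delays to resolve the arrival order
  pr <- stim_protocol(frequencies = c(44, 56), trials_per_condition = 5)
  rec <- simulate_recording(pr, wave_model(source = "O2"),
                            noise_model(background_rms = 3, line_rms = 5),
                            seed = 21)
  ep <- preprocess(rec, spatial_filter = "none")
  delays <- rbind(
    locking_delay(condition_plv(ep, "44", n_surrogates = 60, seed = 1)),
    locking_delay(condition_plv(ep, "56", n_surrogates = 60, seed = 2)))
  src <- select_source(delays, default_montage())
  d <- channel_distances(default_montage(), "O2")
  expect_lte(d[src], 6)      # at/adjacent to the true source
  # arrival order: near-source channels lock no later than frontal ones
  near <- names(d)[d <= 5]; far <- intersect(names(d)[d >= 12],
                                             gradient_electrodes())
  expect_lt(mean(delays[, near], na.rm = TRUE),
            mean(delays[, far], na.rm = TRUE))
})
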
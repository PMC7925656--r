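test_that("windowed phase lags recover the constructed wave geometry", {
  rec <- tiny_session(freqs = 44, trials = 2, seed = 31)
  ep <- preprocess(rec, spatial_filter = "none")
  ph <- phase_series(ep[["44"]])
  lag <- windowed_phase_lag(ph, "Pz", window_center = 0.5)
  expect_equal(unname(lag$lag["Pz"]), 0)
  d <- channel_distances(default_montage(), "Pz")
  k <- 2 * pi * 44 / (100 * model_velocity(wave_model(), 44))
  for (ch in gradient_electrodes())
    expect_lt(abs(wrap_pi_ref(lag$lag[ch] - k * d[ch])), 1e-2)
  expect_error(windowed_phase_lag(ph, "XX"), "unknown source")
  # a window inside the filter edge transient is refused with guidance
  expect_error(windowed_phase_lag(ph, "Pz", window_center = -0.9),
               "later window")
})

test_that("phase lags are equivariant under a constant trial offset", {
  rec <- tiny_session(freqs = 44, trials = 2, seed = 31)
  ep <- preprocess(rec, spatial_filter = "none")
  ph <- phase_series(ep[["44"]])
  lag0 <- windowed_phase_lag(ph, "Pz")$lag
  ph2 <- ph
  ph2$phase[, "Fz", ] <- wrap_pi_ref(ph2$phase[, "Fz", ] + 0.8)
  lag2 <- windowed_phase_lag(ph2, "Pz")$lag
  expect_equal(wrap_pi_ref(lag2["Fz"] - (lag0["Fz"] - 0.8)), c(Fz = 0),
               tolerance = 1e-9)
  expect_equal(lag2["Oz"], lag0["Oz"])
})

test_that("the gradient fit recovers exact lines and flags degeneracy", {
  d <- c(Pz = 0, A = 2, B = 4, C = 6, D = 9)
  lags <- 0.3 * d
  fit <- fit_phase_gradient(lags, d, subset = names(d))
  expect_equal(fit$slope, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  flat <- fit_phase_gradient(setNames(rep(0.5, 5) + c(0, 1e-9, 0, -1e-9, 0),
                                      names(d)),
                             d, subset = names(d))
  expect_lt(abs(flat$slope), 1e-8)
  expect_error(fit_phase_gradient(lags[1:2], d[1:2], names(d)[1:2]),
               "at least 3")
  same <- c(A = 1, B = 1.1, C = 0.9)
  expect_error(fit_phase_gradient(same, c(A = 3, B = 3, C = 3),
                                  names(same)),
               "rank-deficient")
})

test_that("distance-ordered unwrapping beats naive wrapped fitting", {
  # artificial short wavelength (10 cm): true lags exceed pi well inside
  # the montage, so the wrapped lags alias badly
  d <- channel_distances(default_montage(), "Pz")[gradient_electrodes()]
  k <- 2 * pi / 10                       # rad/cm, lambda = 10 cm
  lags <- wrap_pi_ref(k * d)
  fit <- fit_phase_gradient(lags, d)
  expect_equal(fit$slope, k, tolerance = 1e-9)
  naive <- coef(lm(lags ~ d))[2]
  expect_gt(abs(naive - k), 0.1 * k)
})

test_that("phase velocity and wavelength identities hold", {
  expect_equal(phase_velocity(40, distance = 21.6, dphi = 2 * pi), 8.64)
  # slope such that dphi = pi at half a wavelength: v = f * lambda
  lambda <- 23
  expect_equal(phase_velocity(44, slope = 2 * pi / lambda),
               44 * lambda / 100)
  expect_equal(wavelength(8.64, 40), 21.6)
  expect_equal(wavelength(0, 40), 0)
  expect_equal(wavelength(12, 60), 20)
  expect_error(phase_velocity(40, distance = 5, dphi = 0), "undefined")
  expect_error(phase_velocity(40, slope = 0), "undefined")
  expect_error(wavelength(10, 0), "positive")
})

test_that("the velocity-frequency trend is an OLS line", {
  est <- data.frame(freq = c(40, 44, 48, 52), velocity = 0.3 * c(40, 44, 48, 52) + 1)
  tr <- velocity_frequency_trend(est)
  expect_equal(tr$slope, 0.3, tolerance = 1e-12)
  expect_equal(tr$intercept, 1, tolerance = 1e-12)
  expect_equal(tr$r, 1)
  flat <- velocity_frequency_trend(data.frame(freq = c(40, 44, 48),
                                              velocity = c(7, 7, 7)))
  expect_lt(abs(flat$slope), 1e-12)
  expect_error(velocity_frequency_trend(data.frame(freq = 40:41,
                                                   velocity = c(1, 2))),
               "at least 3")
})

test_that("noise-free estimates recover the generator exactly (v = f*lambda)", {
  rec <- tiny_session(freqs = c(40, 44, 60), trials = 2, seed = 33)
  ep <- preprocess(rec, spatial_filter = "none")
  v <- estimate_velocity(ep)
  truth <- model_velocity(wave_model(), c(40, 44, 60))
  expect_equal(v$table$velocity, truth, tolerance = 0.01)
  expect_equal(v$table$wavelength, 100 * v$table$velocity / v$table$freq)
  expect_true(all(v$table$r > 0.999))
})

test_that("doubling the generator velocities doubles the estimates", {
  w2 <- wave_model(v0 = 2 * 8.6, v_slope = 2 * 0.24)
  rec <- tiny_session(freqs = c(40, 60), trials = 2, seed = 34, wave = w2)
  ep <- preprocess(rec, spatial_filter = "none")
  v <- estimate_velocity(ep)
  base <- model_velocity(wave_model(), c(40, 60))
  expect_equal(v$table$velocity, 2 * base, tolerance = 0.01)
})

test_that("the folding factor scales reported velocities only", {
  rec <- tiny_session(freqs = c(40, 44, 60), trials = 2, seed = 33)
  ep <- preprocess(rec, spatial_filter = "none")
  v1 <- estimate_velocity(ep)
  v2 <- estimate_velocity(ep, folding_factor = 2.2)
  expect_equal(v2$table$velocity, 2.2 * v1$table$velocity)
  expect_true(v2$folding_factor_applied)
  expect_equal(v2$table$slope_rad_per_cm, v1$table$slope_rad_per_cm)
})

test_that("the Laplacian suppresses spatially shared activity more than CAR", {
  # With a volume-conduction-like smooth shared noise component, distant
  # channels stay correlated under the common average reference; the
  # surface Laplacian's spatial high-pass breaks that shared structure up.
  # (This is the mechanism behind spurious stimulus-free phase topographies
  # under CAR; the generator does not model biophysical volume conduction
  # itself, so the suppression ratio is the testable property.)
  pr <- stim_protocol(frequencies = 44, trials_per_condition = 4)
  nz <- noise_model(background_rms = 15, line_rms = 0, spatial_scale = 8)
  m <- default_montage()
  xyz <- cbind(cos(m$lat) * sin(m$lon), cos(m$lat) * cos(m$lon),
               sin(m$lat))
  ang <- matrix(acos(pmin(1, pmax(-1, as.vector(tcrossprod(xyz))))), 32)
  far <- ang * 9 > 8 & upper.tri(ang)
  for (s in 1:3) {
    rec <- simulate_recording(pr, wave_model(amplitude = 0), nz,
                              seed = 60 + s)
    ccar <- mean(abs(cor(car_reference(rec$data))[far]))
    clap <- mean(abs(cor(surface_laplacian(rec$data, m))[far]))
    expect_lt(clap, ccar)
  }
})
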
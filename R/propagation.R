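#' Default electrode set for phase-gradient fitting
#'
#' Parieto-occipital-to-frontal midline band covering the sites where the
#' high-frequency SSVEP response is generated and propagates.
#'
#' @return character vector of channel labels.
#' @export
gradient_electrodes <- function() {
  c("O1", "O2", "Oz", "PO3", "PO4", "P3", "Pz", "P4", "CP1", "CP2", "Cz",
    "FC1", "FC2", "Fz")
}

#' Windowed source-relative phase lag per channel
#'
#' Circular mean, over trials and over a window of `n_cycles` stimulation
#' cycles centred at `window_center`, of the wrapped phase difference
#' between the source channel and each channel.  Positive lag means the
#' channel's phase trails the source (outward propagation).
#'
#' @param ph an `ssvep_phase` from [phase_series()].
#' @param source source channel label.
#' @param window_center window centre, s from stimulus onset (default 0.25,
#'   when the steady-state response is already stable).
#' @param n_cycles window length in stimulation cycles (default 5).
#' @return an object of class `ssvep_phaselag`: named `lag` vector
#'   (radians, wrapped, source = 0) plus window metadata.
#' @export
windowed_phase_lag <- function(ph, source, window_center = 0.25,
                               n_cycles = 5) {
  stopifnot(inherits(ph, "ssvep_phase"))
  si <- match(source, ph$channel_names)
  if (is.na(si)) stop("unknown source channel: ", source)
  hw <- n_cycles / ph$freq / 2
  idx <- which(ph$t >= window_center - hw & ph$t <= window_center + hw)
  if (!length(idx)) stop("empty lag window")
  if (!all(ph$valid[idx]))
    stop("lag window touches filter-edge invalid samples; ",
         "choose a later window centre")
  src <- ph$phase[, si, idx, drop = FALSE]
  C <- dim(ph$phase)[2]
  lag <- vapply(seq_len(C), function(c) {
    Arg(mean(exp(1i * (src - ph$phase[, c, idx, drop = FALSE]))))
  }, numeric(1))
  names(lag) <- ph$channel_names
  structure(list(lag = lag, source = source,
                 window_center = window_center, n_cycles = n_cycles,
                 freq = ph$freq),
            class = "ssvep_phaselag")
}

#' Fit the spatial phase gradient (first-order polynomial)
#'
#' Ordinary least squares of the source-relative phase lag against
#' great-circle distance from the source over the selected electrodes.
#' Lags are unwrapped along electrodes sorted by increasing distance before
#' fitting (gradients steeper than pi between neighbours would otherwise
#' alias), and the fit is unconstrained (free intercept, signed lags).
#'
#' @param lags an `ssvep_phaselag` or a named vector of lags (radians).
#' @param distances named vector of distances from the source, cm
#'   (from [channel_distances()]).
#' @param subset electrode labels used for the fit (default
#'   [gradient_electrodes()] intersected with the available channels).
#' @return an object of class `ssvep_gradient`: `slope` (rad/cm),
#'   `intercept`, Pearson `r`, two-sided `p`, and the ordered electrodes,
#'   distances and unwrapped lags.
#' @export
fit_phase_gradient <- function(lags, distances,
                               subset = gradient_electrodes()) {
  meta <- NULL
  if (inherits(lags, "ssvep_phaselag")) { meta <- lags; lags <- lags$lag }
  subset <- intersect(subset, intersect(names(lags), names(distances)))
  if (length(subset) < 3) stop("gradient fit needs at least 3 electrodes")
  d <- distances[subset]
  l <- lags[subset]
  o <- order(d)
  d <- d[o]; l <- l[o]
  if (max(d) - min(d) < 1e-9)
    stop("rank-deficient fit: all electrodes at the same distance")
  # predictive 1-D unwrap along increasing distance: wrap each lag against
  # the value extrapolated from the electrodes unwrapped so far, so a noisy
  # far electrode cannot cascade a 2*pi error through its successors
  lu <- l
  for (i in seq_along(lu)[-1]) {
    pred <- if (i >= 4 && d[i - 1] > d[1]) {
      b <- stats::lm.fit(cbind(1, d[seq_len(i - 1)]),
                         lu[seq_len(i - 1)])$coefficients
      b[1] + b[2] * d[i]
    } else if (d[i - 1] > 1e-9) {
      # too few points for a line: extrapolate proportionally in distance
      # (the source anchors the lag field at zero)
      lu[i - 1] * d[i] / d[i - 1]
    } else lu[i - 1]
    lu[i] <- pred + wrap_pi(l[i] - pred)
  }
  fit <- lm(lu ~ d)
  ct <- cor.test(d, lu)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value,
                 electrodes = names(d), distances = unname(d),
                 lags = unname(lu),
                 window_center = meta$window_center, freq = meta$freq),
            class = "ssvep_gradient")
}

#' @export
print.ssvep_gradient <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_gradient> %s: slope %.4f rad/cm, r = %.3f, ",
                     "p = %.3g (%d electrodes)\n"),
              if (is.null(x$freq)) "" else sprintf("%g Hz", x$freq),
              x$slope, x$r, x$p, length(x$electrodes)))
  invisible(x)
}

#' Phase velocity of the traveling wave
#'
#' `v = 2 * pi * f * (delta / dphi)`: the speed at which the phase front
#' moves over the scalp, from either an explicit distance/phase-difference
#' pair or a fitted spatial phase gradient (`v = 2 * pi * f / slope` with
#' the slope in rad/m).
#'
#' @param f stimulation frequency, Hz.
#' @param distance electrode separation, cm (with `dphi`).
#' @param dphi phase difference over `distance`, radians; must be non-zero.
#' @param slope alternatively, spatial phase gradient in rad/cm (an
#'   `ssvep_gradient` is also accepted).
#' @return phase velocity in m/s.
#' @export
phase_velocity <- function(f, distance = NULL, dphi = NULL, slope = NULL) {
  if (!is.null(slope)) {
    if (inherits(slope, "ssvep_gradient")) slope <- slope$slope
    if (slope == 0) stop("undefined velocity: zero phase gradient")
    return(2 * pi * f / (100 * slope))
  }
  if (is.null(distance) || is.null(dphi))
    stop("give either slope or both distance and dphi")
  if (any(dphi == 0))
    stop("undefined velocity: zero phase difference (infinite speed)")
  2 * pi * f * (distance / 100) / dphi
}

#' Wavelength of the scalp wave
#' @param v phase velocity, m/s.
#' @param f frequency, Hz (> 0).
#' @return wavelength in cm (`100 * v / f`).
#' @export
wavelength <- function(v, f) {
  if (any(f <= 0)) stop("frequency must be positive")
  100 * v / f
}

#' Linear trend of phase velocity over stimulation frequency
#'
#' @param estimates data frame with columns `freq` and `velocity` (an
#'   `ssvep_velocity` object is also accepted).
#' @return list with `slope` ((m/s)/Hz), `intercept` (m/s), Pearson `r`,
#'   two-sided `p` and the number of conditions used.
#' @export
velocity_frequency_trend <- function(estimates) {
  if (inherits(estimates, "ssvep_velocity")) estimates <- estimates$table
  est <- estimates[is.finite(estimates$velocity), , drop = FALSE]
  if (nrow(est) < 3)
    stop("velocity-frequency trend needs at least 3 conditions")
  fit <- lm(velocity ~ freq, data = est)
  if (sd(est$velocity) > 0) {
    ct <- cor.test(est$freq, est$velocity)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_      # flat line: correlation undefined
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, p = p, n = nrow(est))
}

#' Per-condition phase-velocity estimation from epoched data
#'
#' For each condition: narrowband phase series, windowed source-relative
#' phase lags, spatial gradient fit over the electrode subset, and the
#' velocity `2*pi*f/slope` with wavelength `100*v/f`.
#'
#' @param epochs_by_cond named list of `ssvep_epochs` per condition.
#' @param m a [montage()].
#' @param source source channel label (default `"Pz"`).
#' @param subset electrode labels for the gradient fit.
#' @param window_centers centres (s) of the 5-cycle lag windows; the
#'   per-window lag phasors are pooled circularly before the fit.  The
#'   source-relative phase difference is constant over the steady-state
#'   stimulation period, so the default pools the windows at
#'   0.25, 0.5, ..., 1.75 s; pass a single value (e.g. 0.25) for a
#'   one-window estimate.
#' @param n_cycles see [windowed_phase_lag()].
#' @param folding_factor optional multiplicative cortical-folding
#'   correction applied to reported velocities (default 1 = off).
#' @return an object of class `ssvep_velocity`: `table` is a data frame
#'   (freq, slope_rad_per_cm, intercept, r, p, velocity, wavelength),
#'   `fits` the per-condition `ssvep_gradient`s, `trend` the
#'   velocity-frequency regression (when >= 3 conditions).
#' @export
estimate_velocity <- function(epochs_by_cond, m = default_montage(),
                              source = "Pz",
                              subset = gradient_electrodes(),
                              window_centers = seq(0.25, 1.75, by = 0.25),
                              n_cycles = 5,
                              folding_factor = 1) {
  dist <- channel_distances(m, source)
  rows <- list(); fits <- list()
  for (key in names(epochs_by_cond)) {
    ep <- epochs_by_cond[[key]]
    ph <- phase_series(ep)
    lags <- lapply(window_centers, function(wc)
      windowed_phase_lag(ph, source, wc, n_cycles)$lag)
    pooled <- Arg(Reduce(`+`, lapply(lags, function(l) exp(1i * l))))
    names(pooled) <- ph$channel_names
    lag <- structure(list(lag = pooled, source = source,
                          window_center = window_centers[1],
                          n_cycles = n_cycles, freq = ph$freq),
                     class = "ssvep_phaselag")
    fit <- fit_phase_gradient(lag, dist, subset)
    v <- folding_factor * phase_velocity(ep$freq, slope = fit)
    rows[[key]] <- data.frame(freq = ep$freq, slope_rad_per_cm = fit$slope,
                              intercept = fit$intercept, r = fit$r,
                              p = fit$p, velocity = v,
                              wavelength = wavelength(v, ep$freq))
    fits[[key]] <- fit
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  trend <- if (sum(is.finite(tab$velocity)) >= 3)
    velocity_frequency_trend(tab) else NULL
  structure(list(table = tab, fits = fits, trend = trend, source = source,
                 window_centers = window_centers, n_cycles = n_cycles,
                 folding_factor_applied = folding_factor != 1),
            class = "ssvep_velocity")
}

#' @export
print.ssvep_velocity <- function(x, ...) {
  cat(sprintf("<ssvep_velocity> source %s, window(s) at %s s%s\n", x$source,
              paste(x$window_centers, collapse = ", "),
              if (x$folding_factor_applied) ", folding-corrected" else ""))
  print(x$table, digits = 4)
  if (!is.null(x$trend))
    cat(sprintf("trend: %.3f + %.3f * f m/s (r = %.3f, p = %.3g)\n",
                x$trend$intercept, x$trend$slope, x$trend$r, x$trend$p))
  invisible(x)
}
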
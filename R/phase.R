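# wrap angles into (-pi, pi]
wrap_pi <- function(x) pi - (pi - x) %% (2 * pi)

# memoised filter designs (same spec recurs for every seed/condition)
.bp_cache <- new.env(parent = emptyenv())

# complex frequency response of an FIR kernel at frequencies f (Hz)
.fir_freqz <- function(h, f, rate) {
  k <- seq_along(h) - 1
  exp(-2i * pi * outer(f / rate, k)) %*% h
}

#' Design the narrowband equiripple bandpass for one stimulation frequency
#'
#' Parks-McClellan (equiripple, type-I linear phase) bandpass centred on
#' the stimulation frequency with passband `center +/- 1` Hz, stopbands
#' beyond `center +/- 3` Hz, passband ripple 0.058 and stopband ripple
#' 1e-4 (design grid density factor 20).  The filter order is not fixed a
#' priori: it starts from the standard equiripple order estimate and is
#' incremented until the designed response meets the ripple specification
#' on a dense frequency grid.
#'
#' @param center centre (stimulation) frequency, Hz.
#' @param rate sampling rate, Hz; `center + stop_hw` must be below Nyquist.
#' @param pass_hw,stop_hw passband/stopband half-widths, Hz.
#' @param dpass,dstop passband/stopband ripple.
#' @param density design grid density factor.
#' @param grid_n number of verification grid points (default 4096).
#' @return an object of class `ssvep_bandpass`: symmetric `coef`, odd
#'   `taps`, integer `group_delay` (samples), band edges, and the achieved
#'   ripples.
#' @export
design_bandpass <- function(center, rate, pass_hw = 1, stop_hw = 3,
                            dpass = 0.058, dstop = 1e-4, density = 20,
                            grid_n = 4096) {
  ny <- rate / 2
  if (center + stop_hw >= ny)
    stop(sprintf("design error: upper stopband edge %g Hz not below Nyquist %g Hz",
                 center + stop_hw, ny))
  if (center - stop_hw <= 0)
    stop("design error: lower stopband edge must be positive")
  key <- paste(center, rate, pass_hw, stop_hw, dpass, dstop, density,
               grid_n, sep = "_")
  if (!is.null(.bp_cache[[key]])) return(.bp_cache[[key]])
  dfrac <- (stop_hw - pass_hw) / rate
  n <- ceiling((-20 * log10(sqrt(dpass * dstop)) - 13) / (14.6 * dfrac))
  if (n %% 2 == 1) n <- n + 1
  # dense verification grid over [0, Nyquist) via zero-padded FFT
  fgrid <- (seq_len(grid_n) - 1) * rate / (2 * grid_n)
  achieved <- NULL
  for (try in 1:40) {
    h <- as.numeric(signal::remez(
      n,
      c(0, center - stop_hw, center - pass_hw, center + pass_hw,
        center + stop_hw, ny) / ny,
      c(0, 0, 1, 1, 0, 0),
      w = c(dpass / dstop, 1, dpass / dstop),
      ftype = "bandpass", density = density))
    H <- Mod(fft(c(h, numeric(2 * grid_n - length(h)))))[seq_len(grid_n)]
    in_pass <- fgrid >= center - pass_hw & fgrid <= center + pass_hw
    in_stop <- fgrid <= center - stop_hw | fgrid >= center + stop_hw
    achieved <- list(dpass = max(abs(H[in_pass] - 1)),
                     dstop = max(H[in_stop]))
    if (achieved$dpass <= dpass && achieved$dstop <= dstop) {
      return(.bp_cache[[key]] <- structure(list(center = center, rate = rate,
                            pass = center + c(-1, 1) * pass_hw,
                            stop = center + c(-1, 1) * stop_hw,
                            dpass = dpass, dstop = dstop,
                            coef = h, taps = length(h),
                            group_delay = (length(h) - 1) / 2,
                            achieved = achieved),
                       class = "ssvep_bandpass"))
    }
    n <- n + 6
  }
  stop(sprintf(paste0("design error: spec not met up to order %d ",
                      "(achieved dpass %.3g, dstop %.3g)"),
               n - 2, achieved$dpass, achieved$dstop))
}

#' @export
print.ssvep_bandpass <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_bandpass> %g Hz @ %g Hz rate: %d taps, ",
                     "pass [%g, %g], stop beyond [%g, %g], ",
                     "achieved ripple %.3g/%.2g\n"),
              x$center, x$rate, x$taps, x$pass[1], x$pass[2], x$stop[1],
              x$stop[2], x$achieved$dpass, x$achieved$dstop))
  invisible(x)
}

#' Apply a linear-phase FIR filter with group-delay correction
#'
#' Filters and advances the output by the filter's constant group delay, so
#' a passband sinusoid emerges with no phase shift.  The `(taps-1)/2`
#' samples at each edge are contaminated by the kernel running off the data
#' (the head/tail transients of high-order equiripple filters) and are
#' flagged invalid.
#'
#' @param x numeric vector, samples x channels matrix, or `ssvep_epochs`.
#' @param bp an `ssvep_bandpass` from [design_bandpass()] (any odd-length
#'   symmetric kernel object with `coef` works).
#' @return for vector/matrix input: list with `x` (filtered, same shape)
#'   and `valid` (logical per sample).  For epochs: the epochs object with
#'   filtered `data` and `stim` and a `valid` field.
#' @export
apply_zero_delay <- function(x, bp) {
  h <- bp$coef
  if (inherits(x, "ssvep_epochs")) {
    d <- x$data
    S <- dim(d)[3]
    if (S <= length(h)) stop("signal shorter than the filter")
    M <- matrix(aperm(d, c(3, 1, 2)), S)      # samples x (trials*channels)
    Fm <- .fir_zerophase_mat(h, M, 1L)
    out <- x
    out$data <- aperm(array(Fm, c(S, dim(d)[1], dim(d)[2])), c(2, 3, 1))
    dimnames(out$data) <- dimnames(d)
    out$stim <- t(.fir_zerophase_mat(h, t(x$stim), 1L))
    gd <- (length(h) - 1) / 2
    out$valid <- seq_len(S) > gd & seq_len(S) <= S - gd
    return(out)
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x)) else as.matrix(x)
  if (nrow(X) <= length(h)) stop("signal shorter than the filter")
  Y <- .fir_zerophase_mat(h, X, 1L)
  gd <- (length(h) - 1) / 2
  valid <- seq_len(nrow(X)) > gd & seq_len(nrow(X)) <= nrow(X) - gd
  list(x = if (vec) as.numeric(Y) else Y, valid = valid)
}

# analytic signal of each column via the frequency-domain Hilbert method
.analytic <- function(X) {
  n <- nrow(X)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(X) * w, inverse = TRUE) / n
}

#' Instantaneous phase and envelope via the Hilbert transform
#'
#' Builds the analytic signal `y + i * H[y]` with the frequency-domain
#' discrete Hilbert transform and returns its phase (wrapped to (-pi, pi])
#' and envelope.  Meaningful for narrowband input, i.e. after
#' [apply_zero_delay()].
#'
#' @param x numeric vector or samples x channels matrix.
#' @return list with `phase`, `amplitude` (same shape as `x`) and
#'   `undefined`: logical per channel, TRUE where the signal is identically
#'   zero (phase is then reported as 0, not NaN).
#' @export
instantaneous_phase <- function(x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x)) else as.matrix(x)
  undef <- apply(X, 2, function(col) all(col == 0))
  Z <- .analytic(X)
  ph <- Arg(Z); am <- Mod(Z)
  ph[, undef] <- 0; am[, undef] <- 0
  if (vec)
    list(phase = as.numeric(ph), amplitude = as.numeric(am),
         undefined = unname(undef))
  else
    list(phase = ph, amplitude = am, undefined = undef)
}

#' Wrapped phase difference between two phase arrays
#'
#' `arg(exp(i * (phi1 - phi2)))`, wrapped to (-pi, pi] (the boundary maps
#' to +pi).
#'
#' @param phase1,phase2 numeric arrays of equal shape, radians.
#' @return wrapped difference, same shape.
#' @export
phase_difference <- function(phase1, phase2) {
  if (!identical(dim(phase1), dim(phase2)) ||
      length(phase1) != length(phase2))
    stop("phase arrays must have identical shape")
  wrap_pi(phase1 - phase2)
}

#' Phase-locking value across trials
#'
#' `PLV(t) = |1/N * sum_n exp(i * dphi_n(t))|`: the modulus of the
#' trial-averaged unit phasor of the phase difference.  1 means the phase
#' difference is identical across trials, ~0 means no locking.
#'
#' @param dphi trials x samples matrix (or a vector of per-trial phase
#'   differences for a single sample), radians.
#' @return numeric vector of PLV per sample, in `[0, 1]`.
#' @export
plv <- function(dphi) {
  if (is.null(dim(dphi))) dphi <- matrix(dphi)
  if (nrow(dphi) < 2)
    stop("PLV needs at least 2 trials (degenerate at 1 otherwise)")
  abs(colMeans(exp(1i * dphi)))
}

#' Narrowband phase series of an epoch set
#'
#' Runs every channel and the stimulus trace of an epoch set through the
#' same chain: equiripple bandpass at the condition frequency with
#' group-delay correction, then Hilbert instantaneous phase.  Using the
#' identical filter path for the stimulus reference means both signals see
#' the same (zero) phase distortion.
#'
#' @param epochs an `ssvep_epochs`.
#' @param bp optional `ssvep_bandpass`; default designs one at the
#'   condition frequency.
#' @return an object of class `ssvep_phase`: `phase` and `amplitude`
#'   (trials x channels x samples), `stim_phase` (trials x samples),
#'   `valid` (per-sample logical), plus time axis and metadata.
#' @export
phase_series <- function(epochs, bp = NULL) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  if (is.null(bp)) bp <- design_bandpass(epochs$freq, epochs$rate)
  filt <- apply_zero_delay(epochs, bp)
  d <- filt$data
  Tn <- dim(d)[1]; C <- dim(d)[2]; S <- dim(d)[3]
  M <- matrix(aperm(d, c(3, 1, 2)), S)
  hp <- instantaneous_phase(M)
  ph <- aperm(array(hp$phase, c(S, Tn, C)), c(2, 3, 1))
  am <- aperm(array(hp$amplitude, c(S, Tn, C)), c(2, 3, 1))
  dimnames(ph) <- dimnames(am) <- dimnames(d)
  sp <- instantaneous_phase(t(filt$stim))
  structure(list(phase = ph, amplitude = am,
                 stim_phase = t(sp$phase), valid = filt$valid,
                 t = epochs$t, rate = epochs$rate, freq = epochs$freq,
                 channel_names = epochs$channel_names, bp = bp),
            class = "ssvep_phase")
}

#' Stimulus-locked PLV per channel
#' @param ph an `ssvep_phase` from [phase_series()].
#' @return channels x samples matrix of PLV.
#' @export
stimulus_plv <- function(ph) {
  stopifnot(inherits(ph, "ssvep_phase"))
  C <- dim(ph$phase)[2]
  out <- t(vapply(seq_len(C), function(c)
    plv(phase_difference(ph$phase[, c, ], ph$stim_phase)),
    numeric(dim(ph$phase)[3])))
  rownames(out) <- ph$channel_names
  out
}

#' Surrogate phase-locking statistics (PLS)
#'
#' Significance of the observed stimulus-locked PLV against surrogates
#' built by pairing the target condition's trial phases with trial-shuffled
#' stimulus phases drawn from a randomly selected *other* stimulation
#' condition.  PLS is the proportion of surrogate PLVs exceeding the
#' observed PLV; small PLS means the observed locking is unlikely under
#' the no-association null.
#'
#' @param target an `ssvep_phase` for the condition under test.
#' @param others list of `ssvep_phase` objects for the other conditions
#'   (each filtered at its own frequency); must be non-empty.
#' @param n_surrogates number of surrogates (>= 19; default 200, giving a
#'   PLS resolution of 0.005).
#' @param seed optional integer seed for the surrogate randomization.
#' @return an object of class `ssvep_plv` with `plv` and `pls`
#'   (channels x samples), trial/surrogate counts, `valid`, and metadata.
#' @export
pls_surrogate <- function(target, others, n_surrogates = 200, seed = NULL) {
  stopifnot(inherits(target, "ssvep_phase"))
  if (inherits(others, "ssvep_phase")) others <- list(others)
  if (length(others) < 1)
    stop("surrogate null construction impossible: no other condition")
  if (n_surrogates < 19)
    stop("n_surrogates must be at least 19")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Tn <- dim(target$phase)[1]; C <- dim(target$phase)[2]
  S <- dim(target$phase)[3]
  Zt <- exp(1i * matrix(target$phase, Tn))          # T x (C*S), ch fastest
  col_of_sample <- rep(seq_len(S), each = C)
  Ws <- exp(-1i * target$stim_phase)                # T x S
  obs <- abs(colMeans(Zt * Ws[, col_of_sample, drop = FALSE]))
  counts <- numeric(C * S)
  for (s in seq_len(n_surrogates)) {
    oth <- others[[sample.int(length(others), 1)]]
    To <- dim(oth$stim_phase)[1]
    perm <- sample.int(To, size = Tn, replace = To < Tn)
    W <- exp(-1i * oth$stim_phase[perm, , drop = FALSE])
    sur <- abs(colMeans(Zt * W[, col_of_sample, drop = FALSE]))
    counts <- counts + (sur > obs)
  }
  shape <- function(v) {
    m <- matrix(v, C, S)
    rownames(m) <- target$channel_names
    m
  }
  structure(list(plv = shape(obs), pls = shape(counts / n_surrogates),
                 n_trials = Tn, n_surrogates = n_surrogates,
                 valid = target$valid, t = target$t, freq = target$freq,
                 channel_names = target$channel_names),
            class = "ssvep_plv")
}

#' @export
print.ssvep_plv <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_plv> %g Hz condition: %d channels x %d ",
                     "samples, N = %d trials, %d surrogates\n"),
              x$freq, nrow(x$plv), ncol(x$plv), x$n_trials,
              x$n_surrogates))
  invisible(x)
}

#' Stimulus-locked PLV and PLS for one condition of an epoched session
#'
#' Convenience wrapper: builds the narrowband phase series of the target
#' condition and of all other conditions (surrogate pool), then computes
#' observed PLV and surrogate PLS.
#'
#' @param epochs_by_cond named list of `ssvep_epochs` (one per condition),
#'   as returned by [epoch_extract()] / [preprocess()].
#' @param cond condition frequency (or its name in the list).
#' @param n_surrogates,seed see [pls_surrogate()].
#' @return an `ssvep_plv`.
#' @export
condition_plv <- function(epochs_by_cond, cond, n_surrogates = 200,
                          seed = NULL) {
  key <- as.character(cond)
  if (!key %in% names(epochs_by_cond)) stop("unknown condition: ", cond)
  target <- phase_series(epochs_by_cond[[key]])
  others <- lapply(epochs_by_cond[setdiff(names(epochs_by_cond), key)],
                   phase_series)
  pls_surrogate(target, unname(others), n_surrogates, seed)
}

#' Per-channel phase-locking delay
#'
#' Time from stimulus onset to the first sample at which the channel's PLV
#' exceeds `plv_min` while the surrogate statistic is significant
#' (`PLS <= pls_max`), restricted to filter-valid samples.  `NA` where the
#' PLS never reaches significance (or the PLV never crosses).
#'
#' @param plvser an `ssvep_plv` from [pls_surrogate()]/[condition_plv()].
#' @param plv_min PLV threshold (default 0.5, exceeded strictly).
#' @param pls_max PLS significance threshold (default 0.05, inclusive).
#' @return named numeric vector of delays, s, per channel (NA = never).
#' @export
locking_delay <- function(plvser, plv_min = 0.5, pls_max = 0.05) {
  stopifnot(inherits(plvser, "ssvep_plv"))
  ok <- plvser$t >= 0 & plvser$valid
  vapply(seq_len(nrow(plvser$plv)), function(c) {
    hit <- which(ok & plvser$plv[c, ] > plv_min &
                   plvser$pls[c, ] <= pls_max)
    if (length(hit)) plvser$t[hit[1]] else NA_real_
  }, numeric(1)) -> d
  names(d) <- plvser$channel_names
  d
}

#' Select the propagation source channel from locking delays
#'
#' The source is the channel that locks first in the plurality of
#' conditions; ties are broken by the smaller mean delay across conditions,
#' then by posterior-first channel order (descending great-circle distance
#' from the nasion).  An explicit `override` pins the source regardless of
#' the delays (the analysis convention when one channel is known to lead).
#'
#' @param delays conditions x channels matrix of locking delays (rows =
#'   conditions), e.g. `rbind()` of [locking_delay()] results, or a single
#'   named vector.
#' @param m a [montage()] (for the posterior-first tie-break).
#' @param override optional channel label pinning the source.
#' @return a channel label.
#' @export
select_source <- function(delays, m = default_montage(), override = NULL) {
  if (!is.null(override)) {
    if (!override %in% m$name) stop("unknown source channel: ", override)
    return(override)
  }
  if (is.null(dim(delays))) delays <- matrix(delays, 1,
                                             dimnames = list(NULL,
                                                             names(delays)))
  chans <- colnames(delays)
  if (is.null(chans)) stop("delays must carry channel names")
  if (all(is.na(delays))) stop("no channel has a defined locking delay")
  wins <- numeric(ncol(delays)); names(wins) <- chans
  for (r in seq_len(nrow(delays))) {
    row <- delays[r, ]
    if (all(is.na(row))) next
    mn <- min(row, na.rm = TRUE)
    wins[which(row == mn)] <- wins[which(row == mn)] + 1
  }
  cand <- chans[wins == max(wins)]
  if (length(cand) > 1) {
    md <- colMeans(delays[, cand, drop = FALSE], na.rm = TRUE)
    cand <- cand[md == min(md)]
  }
  if (length(cand) > 1) {
    # posterior first: farthest from the nasion direction (lat 0, lon 0)
    i <- match(cand, m$name)
    dn <- great_circle_distance(m$lat[i], m$lon[i], 0, 0,
                                radius = attr(m, "radius"))
    cand <- cand[order(-dn)]
  }
  cand[1]
}

#' Type-I error calibration of the surrogate PLS test
#'
#' Simulates the independence null: target trial phases drawn uniformly and
#' unrelated to the stimulus phases, surrogate stimulus phases drawn from a
#' second (equally unrelated) condition.  For each replicate the PLS is
#' computed with the package's surrogate machinery and compared with
#' `alpha`; the returned rate estimates the probability of falsely
#' declaring phase locking.
#'
#' @param n_reps number of null replicates (default 500).
#' @param n_trials trials per replicate (default 10).
#' @param n_surrogates surrogates per PLS (default 200).
#' @param alpha significance threshold (default 0.05, inclusive, as in the
#'   locking analysis).
#' @param seed optional integer seed.
#' @return list with the empirical `rate`, its Monte-Carlo standard error
#'   `se`, and the calibration parameters.
#' @export
calibrate_pls <- function(n_reps = 500, n_trials = 10, n_surrogates = 200,
                          alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  mk <- function(ph, stim, freq) {
    structure(list(phase = array(ph, c(n_trials, 1, 1),
                                 dimnames = list(NULL, "Pz", NULL)),
                   amplitude = array(1, c(n_trials, 1, 1)),
                   stim_phase = matrix(stim, n_trials),
                   valid = TRUE, t = 0, rate = 256, freq = freq,
                   channel_names = "Pz"),
              class = "ssvep_phase")
  }
  hits <- vapply(seq_len(n_reps), function(i) {
    target <- mk(runif(n_trials, -pi, pi), runif(n_trials, -pi, pi), 44)
    other <- mk(runif(n_trials, -pi, pi), runif(n_trials, -pi, pi), 56)
    pls_surrogate(target, list(other), n_surrogates)$pls[1, 1] <= alpha
  }, logical(1))
  rate <- mean(hits)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps),
       n_reps = n_reps, n_trials = n_trials,
       n_surrogates = n_surrogates, alpha = alpha)
}
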
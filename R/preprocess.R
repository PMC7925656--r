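#' Zero-phase line-noise notch filter
#'
#' A second-order IIR notch (RBJ biquad, zero exactly on the unit circle at
#' the target frequency) applied forward and backward, so the net filter has
#' zero phase and phase analysis downstream is undistorted.  The default
#' quality factor keeps the two-pass passband loss below 1 dB outside
#' `freq` +/- 2 Hz while removing the line component essentially completely.
#'
#' @param x an [recording()] or a numeric vector/matrix (samples x channels).
#' @param freq notch frequency, Hz (default 50).
#' @param rate sampling rate, Hz; taken from the recording when `x` is one.
#' @param q quality factor (centre frequency / 3 dB bandwidth), default 45.
#' @param include_stim also filter the stimulus trace of a recording
#'   (default FALSE: the photodiode trace carries no line pickup).
#' @return same type as `x`, filtered.
#' @export
notch_filter <- function(x, freq = 50, rate = NULL, q = 45,
                         include_stim = FALSE) {
  if (inherits(x, "ssvep_recording")) {
    out <- x
    out$data <- notch_filter(x$data, freq, x$rate, q)
    if (include_stim)
      out$stim <- as.numeric(notch_filter(matrix(x$stim), freq, x$rate, q))
    return(out)
  }
  if (is.null(rate)) stop("rate must be given for plain numeric input")
  if (freq >= rate / 2)
    stop(sprintf("notch frequency %g Hz at or above Nyquist %g Hz",
                 freq, rate / 2))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x)) else x
  w0 <- 2 * pi * freq / rate
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  Y <- .iir_filtfilt_mat(b, a, X)
  if (!vec) dimnames(Y) <- dimnames(X)
  if (vec) as.numeric(Y) else Y
}

# anti-alias FIR for integer-factor decimation (Hamming-window lowpass,
# odd length => integer group delay compensated in C)
.antialias_fir <- function(rate, target) {
  cutoff <- 0.45 * target / (rate / 2)
  n <- 288                       # ~23 Hz transition at 2048 -> 256 Hz
  as.numeric(signal::fir1(n, cutoff))
}

#' Downsample a recording with anti-alias filtering
#'
#' Zero-phase FIR anti-alias filtering (symmetric kernel, group delay
#' compensated) followed by integer-factor sample picking.  Events and the
#' stimulus trace are re-indexed/decimated consistently.
#'
#' @param rec an [recording()].
#' @param target_rate target sampling rate, Hz; must divide `rec$rate`.
#' @return the decimated [recording()].
#' @export
downsample <- function(rec, target_rate = 256) {
  stopifnot(inherits(rec, "ssvep_recording"))
  if (target_rate > rec$rate) stop("target_rate exceeds the recording rate")
  if (target_rate == rec$rate) return(rec)
  q <- rec$rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("target_rate must divide the recording rate evenly")
  q <- as.integer(round(q))
  h <- .antialias_fir(rec$rate, target_rate)
  Y <- .fir_zerophase_mat(h, rec$data, q)
  stim <- as.numeric(.fir_zerophase_mat(h, matrix(rec$stim), q))
  colnames(Y) <- rec$channel_names
  ev <- rec$events
  if (nrow(ev)) ev$onset <- as.integer(round((ev$onset - 1L) / q) + 1L)
  recording(Y, target_rate, rec$channel_names, stim, ev, rec$ground_truth)
}

# Legendre polynomials P_1..P_nmax evaluated at x (vectorized recursion);
# returns length(x) x nmax matrix
.legendre_upto <- function(x, nmax) {
  P <- matrix(0, length(x), nmax)
  P[, 1] <- x
  if (nmax >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  for (n in 3:nmax)
    P[, n] <- ((2 * n - 1) * x * P[, n - 1] - (n - 1) * P[, n - 2]) / n
  P
}

#' Spherical-spline surface Laplacian transform matrix
#'
#' Builds the channels x channels linear operator that maps scalp
#' potentials (uV) to the spherical-spline surface Laplacian estimate
#' (current source density, uV/cm^2) on the montage's sphere, following the
#' classic spherical-spline construction (spline order `m`, truncated
#' Legendre series, ridge regularization of the spline system).  The
#' operator annihilates the constant vector, so the output is invariant to
#' any reference shift common to all channels.
#'
#' @param m a [montage()].
#' @param order spline order (default 4).
#' @param nterms number of Legendre series terms (default 50).
#' @param lambda regularization added to the spline Gram matrix
#'   (default 1e-5).
#' @return channels x channels matrix.
#' @export
laplacian_matrix <- function(m, order = 4, nterms = 50, lambda = 1e-5) {
  stopifnot(inherits(m, "ssvep_montage"))
  r <- attr(m, "radius")
  xyz <- .montage_xyz(m)
  cosang <- pmin(1, pmax(-1, tcrossprod(xyz)))
  n <- 1:nterms
  P <- .legendre_upto(as.vector(cosang), nterms)
  gw <- (2 * n + 1) / (n * (n + 1))^order / (4 * pi)
  hw <- (2 * n + 1) / (n * (n + 1))^(order - 1) / (4 * pi)
  nc <- nrow(m)
  G <- matrix(P %*% gw, nc, nc)
  H <- matrix(P %*% hw, nc, nc)
  Gi <- solve(G + diag(lambda, nc))
  ones <- rep(1, nc)
  proj <- diag(nc) - tcrossprod(ones, colSums(Gi)) / sum(Gi)
  (H %*% (Gi %*% proj)) / r^2
}

#' Apply the surface Laplacian spatial filter
#'
#' @param x an [recording()], an epochs object from [epoch_extract()], or a
#'   samples x channels matrix with column names.
#' @param montage a [montage()] containing every data channel.
#' @param order,nterms,lambda see [laplacian_matrix()].
#' @return same type as `x` with Laplacian-transformed data (uV/cm^2).
#' @export
surface_laplacian <- function(x, montage = default_montage(), order = 4,
                              nterms = 50, lambda = 1e-5) {
  if (inherits(x, "ssvep_recording")) {
    out <- x
    out$data <- surface_laplacian(x$data, montage, order, nterms, lambda)
    return(out)
  }
  if (inherits(x, "ssvep_epochs")) {
    out <- x
    d <- x$data                              # trials x channels x samples
    L <- .laplacian_for(colnames_or(x$channel_names, d), montage, order,
                        nterms, lambda)
    for (i in seq_len(dim(d)[1]))
      d[i, , ] <- L %*% d[i, , ]
    out$data <- d
    return(out)
  }
  X <- as.matrix(x)
  L <- .laplacian_for(colnames(X), montage, order, nterms, lambda)
  Y <- X %*% t(L)
  colnames(Y) <- colnames(X)
  Y
}

colnames_or <- function(nm, d) if (is.null(nm)) dimnames(d)[[2]] else nm

.laplacian_for <- function(chans, montage, order, nterms, lambda) {
  if (is.null(chans)) stop("data must carry channel names")
  missing <- setdiff(chans, montage$name)
  if (length(missing))
    stop("channel(s) missing from montage: ",
         paste(missing, collapse = ", "))
  idx <- match(chans, montage$name)
  sub <- montage(montage$name[idx], montage$lat[idx], montage$lon[idx],
                 radius = attr(montage, "radius"))
  laplacian_matrix(sub, order, nterms, lambda)
}

#' Common-average re-reference
#'
#' Subtracts the instantaneous mean across channels.  Provided only for
#' contrasting volume-conduction artefacts against the surface Laplacian;
#' the analysis pipeline default is the Laplacian.
#'
#' @param x an [recording()] or samples x channels matrix.
#' @return same type as `x`.
#' @export
car_reference <- function(x) {
  if (inherits(x, "ssvep_recording")) {
    out <- x
    out$data <- car_reference(x$data)
    return(out)
  }
  x - rowMeans(x)
}

#' Extract stimulus-locked epochs per condition
#'
#' Cuts the recording into non-overlapping windows time-locked to each
#' event onset (default -1 s to +3 s, covering 1 s pre-stimulus, 2 s
#' stimulation and 1 s post-offset) and groups trials by condition
#' frequency.  Events whose window would leave the recording are dropped
#' with a warning, never silently.
#'
#' @param rec an [recording()].
#' @param window epoch window relative to onset, s, `c(start, end)`.
#' @return named list (one entry per condition frequency, ascending) of
#'   `ssvep_epochs` objects: `data` is trials x channels x samples, `stim`
#'   trials x samples, `t` the epoch time axis (s, 0 = onset).
#' @export
epoch_extract <- function(rec, window = c(-1, 3)) {
  stopifnot(inherits(rec, "ssvep_recording"))
  if (diff(window) <= 0) stop("empty epoch window")
  n <- nrow(rec$data)
  off0 <- round(window[1] * rec$rate)
  ns <- round(diff(window) * rec$rate)
  keep <- rec$events$onset + off0 >= 1 &
    rec$events$onset + off0 + ns - 1 <= n
  if (any(!keep))
    warning(sum(!keep), " event(s) dropped: epoch window exceeds recording")
  ev <- rec$events[keep, , drop = FALSE]
  if (!nrow(ev)) stop("no events with a complete epoch window")
  tt <- (seq_len(ns) - 1 + off0) / rec$rate
  out <- list()
  for (f in sort(unique(ev$freq))) {
    ons <- ev$onset[ev$freq == f]
    d <- array(0, c(length(ons), ncol(rec$data), ns),
               dimnames = list(NULL, rec$channel_names, NULL))
    s <- matrix(0, length(ons), ns)
    for (i in seq_along(ons)) {
      idx <- (ons[i] + off0):(ons[i] + off0 + ns - 1L)
      d[i, , ] <- t(rec$data[idx, , drop = FALSE])
      s[i, ] <- rec$stim[idx]
    }
    out[[as.character(f)]] <- structure(
      list(data = d, stim = s, rate = rec$rate, t = tt, freq = f,
           channel_names = rec$channel_names, t0 = window[1]),
      class = "ssvep_epochs")
  }
  out
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  cat(sprintf(paste0("<ssvep_epochs> %g Hz condition: %d trials x %d",
                     " channels x %d samples @ %g Hz, t in [%g, %g] s\n"),
              x$freq, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$rate, min(x$t), max(x$t)))
  invisible(x)
}

#' Run the preprocessing chain on a continuous recording
#'
#' Applies, in order: line-noise notch, downsampling, the chosen spatial
#' filter (surface Laplacian, common average reference, or none), and
#' stimulus-locked epoching.  The order is fixed and each stage logs its
#' parameters via `message()`.
#'
#' @param rec an [recording()].
#' @param montage a [montage()].
#' @param notch_freq notch frequency, Hz; `NULL` skips the notch.
#' @param notch_q notch quality factor.
#' @param target_rate decimation target, Hz.
#' @param spatial_filter one of `"laplacian"`, `"car"`, `"none"`.
#' @param window epoch window, s.
#' @param verbose emit per-stage messages (default FALSE).
#' @return named list of `ssvep_epochs` (see [epoch_extract()]).
#' @export
preprocess <- function(rec, montage = default_montage(), notch_freq = 50,
                       notch_q = 45, target_rate = 256,
                       spatial_filter = c("laplacian", "car", "none"),
                       window = c(-1, 3), verbose = FALSE) {
  spatial_filter <- match.arg(spatial_filter)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(notch_freq)) {
    say("notch: %g Hz (Q = %g) on %d x %d", notch_freq, notch_q,
        nrow(rec$data), ncol(rec$data))
    rec <- notch_filter(rec, notch_freq, q = notch_q)
  }
  say("downsample: %g -> %g Hz", rec$rate, target_rate)
  rec <- downsample(rec, target_rate)
  if (spatial_filter == "laplacian") {
    say("spatial filter: surface Laplacian")
    rec <- surface_laplacian(rec, montage)
  } else if (spatial_filter == "car") {
    say("spatial filter: common average reference")
    rec <- car_reference(rec)
  }
  say("epoching: [%g, %g] s around %d events", window[1], window[2],
      nrow(rec$events))
  epoch_extract(rec, window)
}
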
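#' Short-time Fourier power of an epoch set
#'
#' Hanning-tapered short-time FFT power on a fractional-hop window grid:
#' window start indices are the nearest samples to an exact fractional grid
#' `hop_samples * (0:(nwin-1))`.  With the defaults (126-sample window,
#' 4.5-sample hop) a 1024-sample epoch at 256 Hz yields 200 windows.
#'
#' @param epochs an `ssvep_epochs` object from [epoch_extract()].
#' @param win_samples analysis window length, samples (default 126).
#' @param hop_samples hop between window starts, samples; may be
#'   fractional (default 4.5).
#' @return an object of class `ssvep_stft`: `power` is a trials x channels
#'   x windows x bins array, `freqs` the FFT bin frequencies (Hz),
#'   `centers` the window-centre times (s).
#' @export
stft_power <- function(epochs, win_samples = 126, hop_samples = 4.5) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  d <- epochs$data
  S <- dim(d)[3]
  if (win_samples > S) stop("analysis window longer than the epoch")
  nwin <- floor((S - win_samples) / hop_samples) + 1
  starts <- round(hop_samples * (seq_len(nwin) - 1))
  taper <- 0.5 * (1 - cos(2 * pi * (0:(win_samples - 1)) /
                            (win_samples - 1)))
  nb <- floor(win_samples / 2) + 1
  Tn <- dim(d)[1]; C <- dim(d)[2]
  pw <- array(0, c(Tn, C, nwin, nb))
  for (w in seq_len(nwin)) {
    idx <- (starts[w] + 1):(starts[w] + win_samples)
    seg <- d[, , idx, drop = FALSE]                 # T x C x win
    M <- t(matrix(seg, Tn * C, win_samples)) * taper
    Fm <- stats::mvfft(M)
    pw[, , w, ] <- array(t(Mod(Fm[seq_len(nb), , drop = FALSE])^2),
                         c(Tn, C, nb))
  }
  structure(list(power = pw,
                 freqs = (seq_len(nb) - 1) * epochs$rate / win_samples,
                 centers = epochs$t[starts + 1] +
                   (win_samples - 1) / (2 * epochs$rate),
                 rate = epochs$rate, freq = epochs$freq,
                 channel_names = epochs$channel_names),
            class = "ssvep_stft")
}

#' Event-related synchronization (percent power change) map
#'
#' Percent power change at the condition fundamental relative to the
#' pre-stimulus baseline window: power is averaged over trials first, then
#' over all STFT windows whose centres fall in each 250 ms span, and the
#' ERS of window w is `100 * (P_w - P_base) / P_base`.  The baseline window
#' itself is 0 by construction.
#'
#' @param stft an `ssvep_stft` from [stft_power()].
#' @param frequency frequency of interest, Hz (default: the condition
#'   fundamental); power is read from the single nearest FFT bin, or the
#'   sum of the 3 nearest bins with `bins = "sum3"`.
#' @param baseline baseline window, s, default `c(-0.25, 0)`.
#' @param response_end end of the response span, s; response windows tile
#'   `[0, response_end]` in steps of the baseline width.
#' @param bins `"nearest"` (default) or `"sum3"`.
#' @return an object of class `ssvep_ers`: `values` is channels x windows
#'   (percent, first window = baseline = 0), `window_edges` the window
#'   start/end times in s.
#' @export
ers_map <- function(stft, frequency = NULL, baseline = c(-0.25, 0),
                    response_end = 1, bins = c("nearest", "sum3")) {
  stopifnot(inherits(stft, "ssvep_stft"))
  bins <- match.arg(bins)
  f <- if (is.null(frequency)) stft$freq else frequency
  k <- which.min(abs(stft$freqs - f))
  sel <- if (bins == "sum3")
    intersect(seq_along(stft$freqs), (k - 1):(k + 1)) else k
  # trial-mean power first, then sum over the selected bin(s): ch x windows
  tmp <- apply(stft$power[, , , sel, drop = FALSE], c(2, 3, 4), mean)
  p <- if (length(dim(tmp)) == 3) apply(tmp, c(1, 2), sum) else tmp
  width <- diff(baseline)
  edges <- c(baseline[1], seq(0, response_end, by = width))
  nw <- length(edges) - 1
  vals <- matrix(0, dim(p)[1], nw,
                 dimnames = list(stft$channel_names, NULL))
  in_base <- stft$centers >= baseline[1] & stft$centers < baseline[2]
  if (!any(in_base)) stop("no STFT windows in the baseline interval")
  pbase <- rowMeans(p[, in_base, drop = FALSE])
  if (any(pbase <= 0))
    stop("zero baseline power in channel(s): ",
         paste(stft$channel_names[pbase <= 0], collapse = ", "))
  for (w in 2:nw) {
    in_w <- stft$centers >= edges[w] & stft$centers < edges[w + 1]
    if (!any(in_w)) stop("no STFT windows in response window ", w - 1)
    vals[, w] <- 100 * (rowMeans(p[, in_w, drop = FALSE]) - pbase) / pbase
  }
  structure(list(values = vals,
                 window_edges = cbind(start = edges[-length(edges)],
                                      end = edges[-1]),
                 frequency = stft$freqs[k], condition = stft$freq,
                 channel_names = stft$channel_names),
            class = "ssvep_ers")
}

#' @export
print.ssvep_ers <- function(x, ...) {
  cat(sprintf("<ssvep_ers> %g Hz condition (bin %.2f Hz), %d channels x %d windows\n",
              x$condition, x$frequency, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Tabulate an ERS map
#' @param x an `ssvep_ers`.
#' @param ... unused.
#' @return data frame with channel, window_start_ms, window_end_ms,
#'   percent_change.
#' @export
as.data.frame.ssvep_ers <- function(x, ...) {
  nw <- ncol(x$values)
  data.frame(
    channel = rep(x$channel_names, nw),
    window_start_ms = rep(x$window_edges[, 1] * 1000, each = nrow(x$values)),
    window_end_ms = rep(x$window_edges[, 2] * 1000, each = nrow(x$values)),
    percent_change = as.vector(x$values))
}
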
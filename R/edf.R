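# Minimal classic-EDF (European Data Format) writer/reader: ASCII header,
# 16-bit little-endian data records.  Supports exactly what the package
# needs for interchange: continuous multichannel signals at one common rate.
# Quantization to 16 bits and tail padding to a whole number of 1 s records
# make the roundtrip lossy by design; events travel in a sidecar TSV.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Export a recording to EDF
#'
#' Writes the EEG channels plus the stimulus trace as a classic EDF file
#' with 1 s data records and 16-bit quantization (lossy; relative error
#' bounded by half a quantization step of each channel's range).  The tail
#' is zero-padded to a whole record.  Events are written to a sidecar file
#' `<path>.events.tsv` which [read_edf()] picks up when present.
#'
#' @param rec an [recording()].
#' @param path output path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ssvep_recording"))
  if (rec$rate != round(rec$rate))
    stop("EDF export requires an integer sampling rate")
  X <- cbind(rec$data, Stim = rec$stim)
  labels <- c(rec$channel_names, "Stim")
  ns <- ncol(X)
  spr <- as.integer(rec$rate)                 # samples per 1 s record
  n_rec <- as.integer(ceiling(nrow(X) / spr))
  pad <- n_rec * spr - nrow(X)
  if (pad > 0) X <- rbind(X, matrix(0, pad, ns))
  pmin_ <- apply(X, 2, min); pmax_ <- apply(X, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(.edf_pad("0", 8),
                .edf_pad("X X X X", 80),
                .edf_pad("Startdate X X X X", 80),
                "01.01.26", "00.00.00",
                .edf_pad(256 * (1 + ns), 8),
                .edf_pad("", 44),
                .edf_pad(n_rec, 8),
                .edf_pad(1, 8),
                .edf_pad(ns, 4))
  fld <- function(vals, width)
    paste(vapply(vals, .edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
                fld(labels, 16),
                fld(rep("", ns), 80),
                fld(rep("uV", ns), 8),
                fld(formatC(pmin_, format = "g", digits = 7), 8),
                fld(formatC(pmax_, format = "g", digits = 7), 8),
                fld(rep(dmin, ns), 8),
                fld(rep(dmax, ns), 8),
                fld(rep("", ns), 80),
                fld(rep(spr, ns), 8),
                fld(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  # re-read declared physical bounds so scaling matches what a reader sees
  pmin_ <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_ <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    block <- vapply(seq_len(ns), function(s) {
      as.integer(round((X[rows, s] - pmin_[s]) * scale[s]) + dmin)
    }, integer(spr))
    writeBin(as.vector(block), con, size = 2, endian = "little")
  }
  if (nrow(rec$events)) {
    write.table(rec$events, paste0(path, ".events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a recording from EDF
#'
#' Reads a classic EDF file written by [write_edf()] (one common sampling
#' rate across signals; a signal labelled `Stim` is mapped back to the
#' stimulus trace).  A truncated or malformed file raises an explicit error.
#'
#' @param path EDF file path.
#' @return an [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  if (sz < 256) stop("malformed EDF file ", path, ": header truncated")
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec))
    stop("malformed EDF file ", path, ": bad header counts")
  if (sz < 256 * (1 + ns)) stop("malformed EDF file ", path,
                                ": signal header truncated")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF file ", path, ": signals have differing rates")
  expected <- hdr_bytes + n_rec * sum(spr) * 2
  if (sz < expected)
    stop("malformed EDF file ", path, ": truncated data (", sz, " of ",
         expected, " bytes)")
  rate <- spr[1] / dur
  n <- n_rec * spr[1]
  X <- matrix(0, n, ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[s], size = 2, endian = "little")
      X[rows, s] <- (dig - dmin[s]) / (dmax[s] - dmin[s]) *
        (pmax_[s] - pmin_[s]) + pmin_[s]
    }
  }
  stim_col <- match("Stim", labels)
  ev_path <- paste0(path, ".events.tsv")
  events <- if (file.exists(ev_path))
    read.table(ev_path, header = TRUE, sep = "\t")
  else data.frame(onset = integer(), freq = numeric())
  if (!is.na(stim_col)) {
    recording(X[, -stim_col, drop = FALSE], rate, labels[-stim_col],
              X[, stim_col], events)
  } else {
    recording(X, rate, labels, numeric(n), events)
  }
}
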
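# Minimal EDF (European Data Format) I/O: fixed-rate continuous multichannel
# signals, 16-bit samples, one data record per second. Covers exactly what
# the BIDS round-trip needs; no annotations, no EDF+ discontinuities.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space-padded
}

#' Write a multichannel signal to an EDF file
#'
#' 16-bit encoding with a declared physical range of +/-`phys_max`
#' microvolts; samples outside the range are clipped. The signal is
#' truncated to a whole number of 1-second data records.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (samples per data record).
#' @param path Output file path.
#' @param channel_names Character vector of channel labels.
#' @param phys_max Physical range bound in microvolts (default 800).
#' @return Invisibly, the path.
#' @export
write_edf <- function(signal, fs, path, channel_names = rownames(signal),
                      phys_max = 800) {
  stopifnot(is.matrix(signal), length(channel_names) == nrow(signal))
  ns <- nrow(signal)
  n_rec <- floor(ncol(signal) / fs)
  if (n_rec < 1) stop("signal shorter than one 1-second EDF record")
  signal <- signal[, seq_len(n_rec * fs), drop = FALSE]
  dig <- round(pmin(pmax(signal, -phys_max), phys_max) / phys_max * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(hdr,
    field(channel_names, 16), field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(rep(format(-phys_max), ns), 8), field(rep(format(phys_max), ns), 8),
    field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
    field(rep("", ns), 80), field(rep(fs, ns), 8), field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    block <- t(dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE])
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain 16-bit EDF)
#'
#' @param path EDF file path.
#' @return List with `signal` (channels x samples matrix in physical units),
#'   `fs`, and `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  off <- pmax_ - scale * dmax_
  out <- out * scale + off
  rownames(out) <- labels
  list(signal = out, fs = spr[1] / rec_dur, channel_names = labels)
}
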
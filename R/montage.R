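#' Standard 19-channel 10-20 montage
#'
#' Builds the electrode montage used throughout the package: the 19 scalp
#' positions of the international 10-20 system (A1/A2 references excluded),
#' with planar coordinates from an azimuthal-equidistant projection onto the
#' unit head disc (x towards the right ear, y towards the nasion).
#'
#' @return An object of class `eeg_montage`: a data.frame with columns
#'   `channel`, `x`, `y`, one row per electrode, in the fixed channel order
#'   Fp1, F7, F3, T3, C3, T5, P3, O1, Fz, Cz, Pz, Fp2, F4, F8, C4, T4, P4,
#'   T6, O2.
#' @examples
#' m <- montage_1020()
#' nrow(m)  # 19
#' @export
montage_1020 <- function() {
  deg <- function(a) a * pi / 180
  ring <- function(angle_deg, r) c(r * cos(deg(angle_deg)), r * sin(deg(angle_deg)))
  # Outer 10% ring at r = 0.9; mid-ring electrodes interpolated; midline on y axis.
  pos <- rbind(
    Fp1 = ring(108, 0.9),
    F7  = ring(144, 0.9),
    F3  = c(-0.34, 0.41),
    T3  = ring(180, 0.9),
    C3  = c(-0.45, 0.00),
    T5  = ring(216, 0.9),
    P3  = c(-0.34, -0.41),
    O1  = ring(252, 0.9),
    Fz  = c(0.00, 0.45),
    Cz  = c(0.00, 0.00),
    Pz  = c(0.00, -0.45),
    Fp2 = ring(72, 0.9),
    F4  = c(0.34, 0.41),
    F8  = ring(36, 0.9),
    C4  = c(0.45, 0.00),
    T4  = ring(0, 0.9),
    P4  = c(0.34, -0.41),
    T6  = ring(-36, 0.9),
    O2  = ring(-72, 0.9)
  )
  m <- data.frame(channel = rownames(pos), x = pos[, 1], y = pos[, 2],
                  stringsAsFactors = FALSE, row.names = NULL)
  class(m) <- c("eeg_montage", "data.frame")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  stopifnot(nrow(m) == 19L, !anyDuplicated(m$channel),
            all(m$x^2 + m$y^2 <= 1 + 1e-12))
  invisible(m)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("10-20 EEG montage:", nrow(x), "channels\n")
  cat(" ", paste(x$channel, collapse = " "), "\n")
  invisible(x)
}

#' Construct an EEG recording object
#'
#' Container for one subject's labelled multichannel signal. Rows of `signal`
#' are channels in montage order, columns are samples in microvolts.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param group One of `"AD"`, `"FTD"`, `"HC"`.
#' @param fs Sampling rate in Hz (default 500).
#' @param signal Numeric matrix, channels x samples.
#' @param montage An `eeg_montage`; defaults to [montage_1020()].
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, group, fs = 500, signal,
                          montage = montage_1020()) {
  group <- match.arg(group, c("AD", "FTD", "HC"))
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)")
  if (nrow(signal) != nrow(montage))
    stop("signal has ", nrow(signal), " rows but montage has ",
         nrow(montage), " channels")
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive sampling rate")
  rownames(signal) <- montage$channel
  structure(list(subject_id = as.character(subject_id), group = group,
                 fs = fs, signal = signal, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signal)
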
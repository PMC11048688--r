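# Sliding-window segmentation: fixed-length windows with a configurable
# overlap fraction (the study contrasts 50% and 90% overlap of 1 s windows).

#' Windowing specification
#'
#' @param window_length_s Window length in seconds (default 1).
#' @param overlap_fraction Fraction of samples shared by consecutive windows,
#'   in `[0, 1)` (the study uses 0.5 and 0.9).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(window_length_s = 1, overlap_fraction = 0.5) {
  stopifnot(window_length_s > 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(window_length_s = window_length_s,
                 overlap_fraction = overlap_fraction),
            class = "window_spec")
}

window_samples <- function(spec, fs) round(spec$window_length_s * fs)

window_step <- function(spec, fs) {
  step <- round(window_samples(spec, fs) * (1 - spec$overlap_fraction))
  max(step, 1L)
}

#' Number of windows without materialising them
#'
#' `floor((N - w) / step) + 1` where `w` is the window length in samples and
#' `step = round(w * (1 - overlap))`.
#'
#' @param N Total samples available.
#' @param spec A [window_spec()].
#' @param fs Sampling rate in Hz.
#' @return Integer window count.
#' @examples
#' window_count(1500, window_spec(1, 0.9), 500)  # 21
#' @export
window_count <- function(N, spec, fs) {
  w <- window_samples(spec, fs)
  if (N < w)
    stop("recording has ", N, " samples but one window needs ", w)
  as.integer(floor((N - w) / window_step(spec, fs)) + 1)
}

#' Segment a recording into overlapping windows
#'
#' Windows are sample-aligned, 0-based, half-open `[start, start + w)`; the
#' trailing remainder that cannot fill a whole window is discarded, so every
#' window has exactly `window_length_s * fs` samples.
#'
#' @param recording An [eeg_recording()].
#' @param spec A [window_spec()].
#' @return Object of class `window_set`: list with `subject_id`, `group`,
#'   `fs`, `channel_names`, `starts` (0-based sample offsets) and `windows`,
#'   an array of dimension n_windows x channels x window_samples.
#' @export
segment <- function(recording, spec) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(spec, "window_spec"))
  N <- ncol(recording$signal)
  w <- window_samples(spec, recording$fs)
  nwin <- window_count(N, spec, recording$fs)   # errors if N < w
  step <- window_step(spec, recording$fs)
  starts <- (seq_len(nwin) - 1L) * step
  nch <- nrow(recording$signal)
  arr <- array(NA_real_, c(nwin, nch, w))
  for (i in seq_len(nwin)) {
    arr[i, , ] <- recording$signal[, (starts[i] + 1):(starts[i] + w)]
  }
  structure(list(subject_id = recording$subject_id, group = recording$group,
                 fs = recording$fs,
                 channel_names = recording$montage$channel,
                 starts = starts, windows = arr),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("window_set %s [%s]: %d windows x %d channels x %d samples\n",
              x$subject_id, x$group, d[1], d[2], d[3]))
  invisible(x)
}
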
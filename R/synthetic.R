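# Synthetic cohort generation: labelled 19-channel EEG-like recordings with
# class-conditional spectral structure (alpha-dominant controls, globally
# slowed AD, frontally slowed FTD) so the downstream pipeline is testable
# without clinical data.

#' Frequency bands used by the generator (Hz)
#' @keywords internal
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

#' Default class-conditional spectral effects
#'
#' Band-power multipliers applied on top of the common resting-EEG baseline:
#' AD raises delta/theta globally (x1.8) and suppresses alpha (x0.6); FTD
#' raises delta/theta (x1.6) with a smooth frontal weighting; HC is the
#' baseline. The `spatial` field selects how the multiplier is distributed
#' over the scalp.
#'
#' @return Named list with one entry per group, each holding band multipliers
#'   and a spatial mode (`"global"` or `"frontal"`).
#' @export
default_group_effects <- function() {
  list(
    HC  = list(delta = 1.0, theta = 1.0, alpha = 1.0, beta = 1.0, spatial = "global"),
    AD  = list(delta = 1.8, theta = 1.8, alpha = 0.6, beta = 1.0, spatial = "global"),
    FTD = list(delta = 1.6, theta = 1.6, alpha = 1.0, beta = 1.0, spatial = "frontal")
  )
}

#' Specify a synthetic cohort
#'
#' @param n_per_group Named counts for the three groups
#'   (default `c(AD = 36, FTD = 23, HC = 29)`, the deposited cohort's sizes).
#' @param duration_s Per-subject recording length in seconds (default 60).
#' @param fs Sampling rate in Hz (default 500).
#' @param seed Integer seed; together with group and subject index it fully
#'   determines every sample.
#' @param effect Class-conditional band multipliers, see
#'   [default_group_effects()].
#' @param background_exponent Spectral exponent of the 1/f^a background
#'   (default 1, the canonical resting-EEG slope).
#' @param gain_jitter Subject-level multiplicative amplitude jitter
#'   (default 0.1, i.e. a uniform gain in 0.9--1.1) so that windows from one
#'   subject are correlated.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(AD = 36, FTD = 23, HC = 29),
                        duration_s = 60, fs = 500, seed = 1,
                        effect = default_group_effects(),
                        background_exponent = 1, gain_jitter = 0.1) {
  stopifnot(all(c("AD", "FTD", "HC") %in% names(n_per_group)),
            all(n_per_group >= 1), duration_s >= 2, fs > 0,
            gain_jitter >= 0, gain_jitter < 1)
  mult <- unlist(lapply(effect, function(e) unlist(e[c("delta", "theta", "alpha", "beta")])))
  if (any(as.numeric(mult) <= 0)) stop("band multipliers must be > 0")
  structure(list(n_per_group = n_per_group[c("AD", "FTD", "HC")],
                 duration_s = duration_s, fs = fs, seed = as.integer(seed),
                 effect = effect, background_exponent = background_exponent,
                 gain_jitter = gain_jitter),
            class = "cohort_spec")
}

# Baseline per-band RMS amplitudes in microvolts, before group multipliers
# and spatial weights. Alpha is posterior-dominant as in eyes-closed rest.
.base_band_rms <- c(delta = 6, theta = 4, alpha = 9, beta = 3)
.background_rms <- 6
.sensor_noise_rms <- 1.5

# Run expr with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

subject_seed <- function(seed, group, subject_index) {
  g <- match(group, c("AD", "FTD", "HC"))
  as.integer((as.numeric(seed) * 10007 + g * 611953 + subject_index * 7919) %%
               2147483647)
}

# Band-limited Gaussian noise via FFT masking, scaled to unit RMS.
band_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  f <- (0:(n - 1)) / n * fs  # two-sided bin frequencies
  f <- pmin(f, fs - f)
  spec <- stats::fft(w)
  spec[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

# 1/f^a background noise, unit RMS.
pink_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  gain <- ifelse(f < 0.5, 0, f^(-exponent / 2))
  spec <- stats::fft(w) * gain
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Per-channel frontality in [0, 1] from montage y coordinate (1 = nasion).
channel_frontality <- function(montage) {
  pmin(pmax((montage$y + 0.9) / 1.8, 0), 1)
}

# Per-channel band weight matrix (bands x channels) for one group.
band_weights <- function(effect_group, montage) {
  fr <- channel_frontality(montage)
  nch <- nrow(montage)
  # common resting topography: alpha posterior-dominant
  base <- rbind(delta = rep(1, nch), theta = rep(1, nch),
                alpha = 0.5 + (1 - fr), beta = rep(1, nch))
  mult <- vapply(c("delta", "theta", "alpha", "beta"), function(b) {
    m <- effect_group[[b]]
    if (identical(effect_group$spatial, "frontal") && m != 1) {
      1 + (m - 1) * fr^2   # smooth frontal falloff
    } else rep(m, nch)
  }, numeric(nch))
  base * t(mult)
}

#' Generate one synthetic EEG recording
#'
#' Synthesises a 19-channel recording as 1/f-weighted broadband background
#' plus narrowband-filtered Gaussian oscillations in the delta, theta, alpha
#' and beta bands, with per-band amplitudes set by the group's multipliers
#' and spatial weighting, plus white sensor noise and a subject-level gain
#' jitter. Deterministic given `(spec$seed, group, subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"AD"`, `"FTD"` or `"HC"`.
#' @param subject_index Positive integer; distinguishes subjects within a
#'   group.
#' @return An [eeg_recording()].
#' @examples
#' r <- generate_recording(cohort_spec(duration_s = 4), "HC", 1)
#' dim(r$signal)
#' @export
generate_recording <- function(spec, group, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group, c("AD", "FTD", "HC"))
  if (spec$duration_s < 2) stop("duration_s must cover at least two windows")
  montage <- montage_1020()
  n <- round(spec$duration_s * spec$fs)
  nch <- nrow(montage)
  W <- band_weights(spec$effect[[group]], montage)
  bands <- eeg_bands()
  sig <- with_seed(subject_seed(spec$seed, group, subject_index), {
    gain <- 1 + stats::runif(1, -spec$gain_jitter, spec$gain_jitter)
    out <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      x <- .background_rms * pink_noise(n, spec$fs, spec$background_exponent)
      for (b in names(bands)) {
        amp <- .base_band_rms[[b]] * W[b, ch]
        x <- x + amp * band_noise(n, spec$fs, bands[[b]])
      }
      out[ch, ] <- gain * x + .sensor_noise_rms * stats::rnorm(n)
    }
    out
  })
  eeg_recording(sprintf("%s%02d", group, subject_index), group, spec$fs, sig,
                montage)
}

#' Generate a full labelled cohort
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording()] objects, one per subject, with unique
#'   subject ids encoding the group (e.g. `"AD01"`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  for (g in c("AD", "FTD", "HC")) {
    for (i in seq_len(spec$n_per_group[[g]])) {
      recs[[length(recs) + 1L]] <- generate_recording(spec, g, i)
    }
  }
  recs
}

#' Welch-style band power of one channel
#'
#' Average periodogram power within a frequency band, used to check the
#' generator's spectral contract (e.g. alpha dominance over delta at O1 in
#' controls).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric, band edges in Hz.
#' @param seg_s Segment length in seconds for averaging (default 2).
#' @return Mean power spectral density within the band.
#' @export
band_power <- function(x, fs, band, seg_s = 2) {
  nseg <- round(seg_s * fs)
  starts <- seq(1, length(x) - nseg + 1, by = nseg)
  f <- (0:(nseg - 1)) / nseg * fs
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  pw <- vapply(starts, function(s) {
    seg <- x[s:(s + nseg - 1)]
    p <- Mod(stats::fft(seg - mean(seg)))^2 / nseg
    mean(p[keep])
  }, numeric(1))
  mean(pw)
}

#' Write a cohort as a minimal BIDS-style EDF directory
#'
#' Lays out `sub-<id>/eeg/sub-<id>_task-eyesclosed_eeg.edf` per subject plus
#' a `participants.tsv` with columns `participant_id` and `Group` (the
#' single-letter codes A/F/C used by the public accession's layout). Signals
#' are stored as 16-bit EDF with a declared physical range of +/-800 uV;
#' values outside that range are clipped.
#'
#' @param cohort List of [eeg_recording()]s with unique subject ids.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a data.frame manifest with columns `participant_id`,
#'   `Group`, `path`.
#' @export
write_cohort_bids <- function(cohort, directory) {
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id in cohort: ",
                               ids[duplicated(ids)][1])
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  code <- c(AD = "A", FTD = "F", HC = "C")
  rows <- lapply(cohort, function(r) {
    pid <- paste0("sub-", r$subject_id)
    eegdir <- file.path(directory, pid, "eeg")
    dir.create(eegdir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(eegdir, paste0(pid, "_task-eyesclosed_eeg.edf"))
    write_edf(r$signal, r$fs, path, channel_names = r$montage$channel)
    data.frame(participant_id = pid, Group = code[[r$group]], path = path,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), Group = character(),
               path = character(), stringsAsFactors = FALSE)
  utils::write.table(manifest[, c("participant_id", "Group")],
                     file.path(directory, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
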
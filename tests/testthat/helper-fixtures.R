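# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, envir = .fixture_env)) assign(key, make(), .fixture_env)
  get(key, envir = .fixture_env)
}

# Small synthetic cohort: n subjects per group, short recordings.
tiny_cohort <- function(n = 3, duration_s = 6, seed = 7) {
  memo(sprintf("cohort_%d_%d_%d", n, duration_s, seed), function()
    generate_cohort(cohort_spec(
      n_per_group = c(AD = n, FTD = n, HC = n),
      duration_s = duration_s, seed = seed)))
}

# Labelled feature table with a known group separation, bypassing signal
# synthesis: 19 Gaussian feature columns, group mean shift `sep` on all
# channels, plus a per-subject random offset so subject identity matters.
blob_table <- function(n_subj = 8, windows = 40, sep = 2, seed = 1,
                       groups = c("AD", "HC"), subject_sd = 0.3) {
  chans <- montage_1020()$channel
  set.seed(seed)
  rows <- list()
  for (g in groups) for (s in seq_len(n_subj)) {
    mu <- if (g == groups[1]) sep else 0
    off <- rnorm(19, 0, subject_sd)
    X <- matrix(rnorm(windows * 19, mu, 1), windows, 19,
                dimnames = list(NULL, chans))
    X <- sweep(X, 2, off, "+")
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("%s%02d", g, s), group = g,
      window_index = seq_len(windows) - 1L, X,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Feature table where only one channel carries class signal.
planted_table <- function(channel = "O2", n_subj = 6, windows = 30,
                          sep = 2.5, seed = 1) {
  tab <- blob_table(n_subj, windows, sep = 0, seed = seed)
  set.seed(seed + 1)
  tab[tab$group == "AD", channel] <-
    tab[tab$group == "AD", channel] + sep
  tab
}

# Window set with given number of windows built directly from a matrix.
manual_window_set <- function(nwin, nch = 19, w = 100, fill = rnorm) {
  chans <- montage_1020()$channel[seq_len(nch)]
  arr <- array(fill(nwin * nch * w), c(nwin, nch, w))
  structure(list(subject_id = "S1", group = "HC", fs = w,
                 channel_names = chans,
                 starts = (seq_len(nwin) - 1L) * w, windows = arr),
            class = "window_set")
}
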
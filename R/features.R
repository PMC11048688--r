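# Windowed complexity/entropy features, one scalar per channel per window:
# SVD entropy, Higuchi fractal dimension, zero-crossing rate, detrended
# fluctuation analysis, and the Hjorth parameters. All are implemented from
# their defining formulas; established libraries are used only as
# cross-checks in the test suite.

check_window <- function(x, min_len = 2) {
  if (!is.numeric(x) || length(x) < min_len)
    stop("window must be numeric with at least ", min_len, " samples")
  if (!all(is.finite(x))) stop("window contains non-finite samples")
  invisible(x)
}

#' SVD entropy of a single-channel window
#'
#' Shannon entropy (base 2) of the normalised singular values of the
#' time-delay embedding matrix whose rows are lagged vectors of length
#' `order`. A constant (rank-1) window has entropy 0; the upper bound is
#' `log2(order)`, approached by broadband noise. The entropy is not
#' normalised by `log2(order)`.
#'
#' @param x Numeric vector, one channel of one window.
#' @param order Embedding dimension M (default 3).
#' @param delay Embedding lag in samples (default 1).
#' @return Scalar entropy in `[0, log2(order)]`.
#' @examples
#' svd_entropy(rep(5, 100))   # 0
#' @export
svd_entropy <- function(x, order = 3, delay = 1) {
  check_window(x, min_len = (order - 1) * delay + 2)
  stopifnot(order >= 2, delay >= 1)
  n <- length(x) - (order - 1) * delay
  Y <- vapply(seq_len(order), function(j) x[(1:n) + (j - 1) * delay],
              numeric(n))
  # singular values of Y = sqrt of eigenvalues of Y'Y
  ev <- eigen(crossprod(Y), symmetric = TRUE, only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  s[s < max(s) * 1e-7] <- 0   # suppress numerical rank noise
  tot <- sum(s)
  if (tot == 0) return(0)   # all-zero window
  sbar <- s / tot
  sbar <- sbar[sbar > 0]
  -sum(sbar * log2(sbar))
}

#' Higuchi fractal dimension of a single-channel window
#'
#' For every interval length `k` in `1..kmax` and start `m` in `1..k`, forms
#' the subsampled series `x(m), x(m+k), ...` and its normalised curve length
#' `L_m(k) = sum |x(m+ik) - x(m+(i-1)k)| * (N-1) / (floor((N-m)/k) * k) / k`;
#' averages over `m` and estimates the dimension as the slope of
#' `ln L(k)` against `ln(1/k)`. Near 1 for smooth curves, 2 for white noise,
#' 1.5 for Brownian paths.
#'
#' @param x Numeric vector.
#' @param kmax Maximum interval length (default 10).
#' @return Scalar fractal dimension; a constant window returns 1 (a flat
#'   line has dimension 1).
#' @export
higuchi_fd <- function(x, kmax = 10) {
  check_window(x, min_len = 2 * kmax + 1)
  stopifnot(kmax >= 2)
  N <- length(x)
  Lk <- vapply(seq_len(kmax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      nmax <- floor((N - m) / k)
      if (nmax < 1) return(NA_real_)
      idx <- m + (0:nmax) * k
      norm <- (N - 1) / (nmax * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(Lm, na.rm = TRUE)
  }, numeric(1))
  if (all(Lk == 0)) return(1)           # flat line
  keep <- Lk > 0
  if (sum(keep) < 2) return(1)
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[keep])), log(Lk[keep]))
  unname(fit$coefficients[2])
}

#' Zero-crossing rate of a single-channel window
#'
#' Fraction of adjacent sample pairs whose product is strictly negative;
#' pairs containing an exact zero do not count as crossings. Sensitive to
#' sampling phase for signals that touch zero exactly.
#'
#' @param x Numeric vector of length >= 2.
#' @return Scalar rate in `[0, 1]`.
#' @export
zero_crossing_rate <- function(x) {
  check_window(x, min_len = 2)
  T <- length(x)
  sum(x[-1] * x[-T] < 0) / (T - 1)
}

default_dfa_scales <- function(w) {
  s <- unique(round(exp(seq(log(4), log(floor(w / 4)), length.out = 12))))
  s[s >= 4]
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Integrates the mean-centred series, splits the profile into
#' non-overlapping boxes of each scale `n` (trailing partial box discarded),
#' subtracts a least-squares polynomial trend of order `detrend_order` per
#' box, and computes the RMS fluctuation `F(n)`. The exponent alpha is the
#' slope of `log F(n)` against `log n`: 0.5 for white noise, 1.5 for a
#' Brownian path.
#'
#' @param x Numeric vector.
#' @param box_sizes Integer scales; default ~12 log-spaced values in
#'   `[4, floor(length(x)/4)]`.
#' @param detrend_order Polynomial detrend order (default 1, linear).
#' @return Scalar scaling exponent alpha.
#' @export
dfa <- function(x, box_sizes = NULL, detrend_order = 1) {
  check_window(x, min_len = 16)
  w <- length(x)
  if (is.null(box_sizes)) box_sizes <- default_dfa_scales(w)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  stopifnot(length(box_sizes) >= 4, all(box_sizes >= detrend_order + 2),
            all(box_sizes < w))
  y <- cumsum(x - mean(x))
  Fn <- vapply(box_sizes, function(n) {
    nbox <- floor(w / n)
    B <- matrix(y[seq_len(n * nbox)], nrow = n)
    X <- stats::poly(seq_len(n), degree = detrend_order, raw = TRUE)
    X <- cbind(1, X)
    resid <- B - X %*% solve(crossprod(X), crossprod(X, B))
    sqrt(mean(resid^2))
  }, numeric(1))
  if (any(Fn == 0))
    stop("DFA fluctuation is zero at scale n = ",
         box_sizes[which(Fn == 0)[1]], " (signal is polynomial)")
  fit <- stats::lm.fit(cbind(1, log(box_sizes)), log(Fn))
  unname(fit$coefficients[2])
}

#' Hjorth parameters of a single-channel window
#'
#' Activity is the signal variance (uV^2); mobility the square root of the
#' ratio of the first difference's variance to the signal variance
#' (per-sample, dimensionless); complexity the ratio of the difference
#' series' mobility to the signal's mobility.
#'
#' @param x Numeric vector of length >= 3.
#' @return Object of class `hjorth_result`: list with `activity`, `mobility`,
#'   `complexity`.
#' @export
hjorth <- function(x) {
  check_window(x, min_len = 3)
  v0 <- stats::var(x)
  if (v0 == 0) stop("constant window: Hjorth mobility is undefined")
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  structure(list(activity = v0, mobility = mob,
                 complexity = sqrt(v2 / v1) / mob),
            class = "hjorth_result")
}

#' @export
print.hjorth_result <- function(x, ...) {
  cat(sprintf("Hjorth: activity %.4g  mobility %.4g  complexity %.4g\n",
              x$activity, x$mobility, x$complexity))
  invisible(x)
}

#' Single-column Hjorth summary
#'
#' The arithmetic mean of mobility and complexity, collapsing the Hjorth
#' parameters to the one value per channel that the 19-column feature layout
#' requires. Activity is deliberately excluded: it carries physical units
#' while the feature table mixes dimensionless measures.
#'
#' @inheritParams hjorth
#' @return Scalar `(mobility + complexity) / 2`.
#' @export
hjorth_scalar <- function(x) {
  h <- hjorth(x)
  (h$mobility + h$complexity) / 2
}

feature_measures <- c("svd", "hfd", "zcr", "dfa", "hjorth")

feature_fun <- function(measure, cfg = NULL) {
  cfg <- cfg %||% list()
  switch(measure,
    svd = function(x) svd_entropy(x, order = cfg$order %||% 3,
                                  delay = cfg$delay %||% 1),
    hfd = function(x) higuchi_fd(x, kmax = cfg$kmax %||% 10),
    zcr = zero_crossing_rate,
    dfa = function(x) dfa(x, box_sizes = cfg$box_sizes,
                          detrend_order = cfg$detrend_order %||% 1),
    hjorth = hjorth_scalar,
    stop("unknown measure: ", measure))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a per-window, per-channel feature table
#'
#' Applies one measure to every channel of every window. Windows where
#' extraction fails on any channel (e.g. a constant channel for Hjorth) are
#' dropped with a message reporting the count.
#'
#' @param ws A [segment()] window set.
#' @param measure One of `"svd"`, `"hfd"`, `"zcr"`, `"dfa"`, `"hjorth"`.
#' @param cfg Optional list of measure parameters (`order`, `delay`, `kmax`,
#'   `box_sizes`, `detrend_order`).
#' @return A data.frame with columns `subject_id`, `group`, `window_index`,
#'   then one column per channel; attribute `"measure"` records the measure.
#' @export
extract_feature_table <- function(ws, measure = feature_measures, cfg = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(ws, "window_set"))
  f <- feature_fun(measure, cfg)
  d <- dim(ws$windows)
  nwin <- d[1]; nch <- d[2]
  vals <- matrix(NA_real_, nwin, nch, dimnames = list(NULL, ws$channel_names))
  ok <- rep(TRUE, nwin)
  for (i in seq_len(nwin)) {
    row <- tryCatch(
      vapply(seq_len(nch), function(ch) f(ws$windows[i, ch, ]), numeric(1)),
      error = function(e) NULL)
    if (is.null(row) || !all(is.finite(row))) ok[i] <- FALSE
    else vals[i, ] <- row
  }
  if (any(!ok))
    message(sum(!ok), " window(s) dropped during ", measure, " extraction")
  nkeep <- sum(ok)
  out <- data.frame(subject_id = rep(ws$subject_id, nkeep),
                    group = rep(ws$group, nkeep),
                    window_index = which(ok) - 1L,
                    vals[ok, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "measure") <- measure
  out
}

#' Feature table for a whole cohort
#'
#' Segments every recording and stacks the per-subject feature tables.
#'
#' @param cohort List of [eeg_recording()]s.
#' @param wspec A [window_spec()].
#' @inheritParams extract_feature_table
#' @return Combined feature data.frame (see [extract_feature_table()]).
#' @export
cohort_feature_table <- function(cohort, wspec, measure = feature_measures,
                                 cfg = NULL) {
  measure <- match.arg(measure)
  tabs <- lapply(cohort, function(r)
    extract_feature_table(segment(r, wspec), measure, cfg))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  out
}

feature_cols <- function(tab) {
  setdiff(colnames(tab), c("subject_id", "group", "window_index",
                           "label", ".synthetic"))
}
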
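# Per-channel feature importance from trained models, and topographic scalp
# maps of the scores on the 10-20 montage.

new_channel_importance <- function(scores, channel_names, method,
                                   task = NA, measure = NA, overlap = NA) {
  stopifnot(length(scores) == length(channel_names), all(scores >= 0))
  tot <- sum(scores)
  scores <- if (tot > 0) scores / tot else rep(1 / length(scores),
                                               length(scores))
  names(scores) <- channel_names
  # ties broken by montage order (stable sort)
  ranking <- channel_names[order(-scores)]
  structure(list(scores = scores, ranking = ranking, method = method,
                 task = task, measure = measure, overlap = overlap),
            class = "channel_importance")
}

#' @export
print.channel_importance <- function(x, ...) {
  cat("channel_importance (", x$method, "): top channels ",
      paste(utils::head(x$ranking, 5), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Impurity-based channel importance from a tree ensemble
#'
#' Maps the fitted ensemble's impurity importances onto channels and
#' normalises them to sum 1.
#'
#' @param model An [train_classifier()] model of type RF, ET or XGB.
#' @param channel_names Channel names (defaults to the model's feature
#'   columns).
#' @return Object of class `channel_importance` with `scores` (sum 1) and
#'   `ranking` (descending; ties broken by montage order).
#' @export
tree_importance <- function(model, channel_names = model$features) {
  stopifnot(inherits(model, "eeg_classifier"))
  raw <- switch(model$learner,
    RF = ,
    ET = ranger::importance(model$fit)[channel_names],
    XGB = {
      imp <- xgboost::xgb.importance(model = model$fit)
      v <- stats::setNames(rep(0, length(channel_names)), channel_names)
      v[imp$Feature] <- imp$Gain
      v
    },
    stop("learner ", model$learner, " exposes no impurity importances; ",
         "use permutation_importance()"))
  new_channel_importance(pmax(as.numeric(raw), 0), channel_names,
                         method = paste0("impurity:", model$learner))
}

#' Permutation channel importance
#'
#' Mean drop in a metric (default accuracy) on labelled rows when each
#' channel's column is independently shuffled, repeated `n_repeats` times.
#' Negative drops are clipped to zero before normalisation. Works for any
#' fitted model, including KNN.
#'
#' @param model An [train_classifier()] model.
#' @param rows Labelled feature data.frame to evaluate on.
#' @param metric `"accuracy"` or `"auc"`.
#' @param n_repeats Shuffles per channel (default 5).
#' @param seed Integer seed.
#' @return A `channel_importance` object.
#' @export
permutation_importance <- function(model, rows, metric = c("accuracy", "auc"),
                                   n_repeats = 5, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "eeg_classifier"), "label" %in% names(rows))
  if (length(unique(rows$label)) < 2)
    stop("rows contain a single class; ", metric, " is degenerate")
  score_of <- function(pr)
    if (metric == "accuracy")
      classification_metrics(confusion(rows$label, pr$label))$accuracy
    else auc(rows$label, pr$score)
  base <- score_of(predict(model, rows))
  cols <- model$features
  drops <- with_seed(as.integer(seed), {
    vapply(cols, function(cl) {
      mean(vapply(seq_len(n_repeats), function(r) {
        shuf <- rows
        shuf[[cl]] <- sample(shuf[[cl]])
        base - score_of(predict(model, shuf))
      }, numeric(1)))
    }, numeric(1))
  })
  new_channel_importance(pmax(drops, 0), cols,
                         method = paste0("permutation:", metric))
}

#' Ordered channel ranking from an importance object
#'
#' @param imp A `channel_importance`.
#' @return data.frame with `rank`, `channel`, `score`, descending; score
#'   ties are broken by montage order.
#' @export
rank_report <- function(imp) {
  stopifnot(inherits(imp, "channel_importance"))
  data.frame(rank = seq_along(imp$ranking), channel = imp$ranking,
             score = as.numeric(imp$scores[imp$ranking]),
             stringsAsFactors = FALSE)
}

# Thin-plate-spline RBF interpolation of per-electrode values over the unit
# disc; exact at the electrodes.
tps_interpolate <- function(px, py, v, gx, gy) {
  n <- length(px)
  phi <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  D2 <- outer(px, px, function(a, b) (a - b)^2) +
        outer(py, py, function(a, b) (a - b)^2)
  K <- phi(D2)
  P <- cbind(1, px, py)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  w <- solve(A, c(v, 0, 0, 0))
  G2 <- outer(gx, px, function(a, b) (a - b)^2) +
        outer(gy, py, function(a, b) (a - b)^2)
  as.numeric(phi(G2) %*% w[1:n] + w[n + 1] + w[n + 2] * gx + w[n + 3] * gy)
}

#' Interpolated scalp field for an importance map
#'
#' Evaluates the thin-plate interpolant of the channel scores on a square
#' grid, masked to the unit head disc. Exposed separately from
#' [render_topomap()] so the field can be inspected numerically.
#'
#' @param imp A `channel_importance`.
#' @param montage An `eeg_montage` matching the scores.
#' @param grid_n Grid resolution per axis (default 80).
#' @return List with `x`, `y` (grid axes) and `z` (grid_n x grid_n matrix,
#'   `NA` outside the head disc).
#' @export
topomap_field <- function(imp, montage = montage_1020(), grid_n = 80) {
  stopifnot(inherits(imp, "channel_importance"),
            identical(names(imp$scores), montage$channel))
  ax <- seq(-1, 1, length.out = grid_n)
  g <- expand.grid(x = ax, y = ax)
  z <- tps_interpolate(montage$x, montage$y, as.numeric(imp$scores),
                       g$x, g$y)
  z[g$x^2 + g$y^2 > 1] <- NA
  list(x = ax, y = ax, z = matrix(z, grid_n, grid_n))
}

#' Render an importance topomap to a PNG file
#'
#' Head outline with nose and ears, interpolated colour field over the
#' scalp, electrode markers and labels, and a colour scale. The title
#' encodes task, measure and overlap when present in the importance object.
#'
#' @param imp A `channel_importance`.
#' @param montage An `eeg_montage`.
#' @param out_path Output PNG path.
#' @param grid_n Interpolation grid resolution (default 120).
#' @return Invisibly, `out_path`.
#' @export
render_topomap <- function(imp, montage = montage_1020(), out_path,
                           grid_n = 120) {
  fld <- topomap_field(imp, montage, grid_n)
  title <- paste(stats::na.omit(c(imp$task, imp$measure,
    if (!is.na(imp$overlap)) paste0(imp$overlap * 100, "% overlap"))),
    collapse = " | ")
  if (title == "") title <- paste("Channel importance:", imp$method)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  grDevices::png(out_path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 5))
  graphics::image(fld$x, fld$y, fld$z, col = pal, asp = 1, axes = FALSE,
                  xlab = "", ylab = "", main = title,
                  xlim = c(-1.25, 1.25), ylim = c(-1.15, 1.25))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), lwd = 2)
  graphics::lines(c(-0.1, 0, 0.1), c(0.995, 1.12, 0.995), lwd = 2)  # nose
  for (s in c(-1, 1))                                               # ears
    graphics::lines(s * (1 + 0.06 * cos(th) * 0.8), 0.12 * sin(th), lwd = 2)
  graphics::points(montage$x, montage$y, pch = 21, bg = "white", cex = 1.4)
  graphics::text(montage$x, montage$y + 0.07, montage$channel, cex = 0.7)
  zr <- range(fld$z, na.rm = TRUE)
  ylv <- seq(-0.8, 0.8, length.out = 65)
  graphics::rect(1.12, ylv[-65], 1.2, ylv[-1], col = pal, border = NA)
  graphics::text(1.22, c(-0.8, 0.8), signif(zr, 2), adj = 0, cex = 0.7)
  invisible(out_path)
}
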
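# Subject-disjoint splitting, subject-wise cross-validation folds, and
# SMOTE oversampling of the minority class. The subject-level split is the
# study's central safeguard against leakage: no subject may contribute
# windows to both train and test.

#' Make a subject-disjoint train/test split with CV folds
#'
#' Splits subjects (not rows) into train and test, stratified by group where
#' counts allow, and assigns every training subject to exactly one of
#' `n_folds` cross-validation hold-out folds (round-robin per group).
#' Rounding ties in the 80:20 split are resolved toward the larger training
#' set.
#'
#' @param subjects data.frame with columns `subject_id`, `group` (one row
#'   per subject), or a list of [eeg_recording()]s.
#' @param test_fraction Fraction of subjects held out for testing
#'   (default 0.2).
#' @param n_folds Number of CV folds over the training subjects
#'   (default 15).
#' @param seed Integer seed; the plan is fully reproducible from it.
#' @return Object of class `split_plan`: list with `train_subjects`,
#'   `test_subjects`, `folds` (list of subject-id vectors), `seed`.
#' @export
make_split <- function(subjects, test_fraction = 0.2, n_folds = 15, seed = 1) {
  if (is.list(subjects) && !is.data.frame(subjects))
    subjects <- data.frame(
      subject_id = vapply(subjects, function(r) r$subject_id, ""),
      group = vapply(subjects, function(r) r$group, ""),
      stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "group") %in% names(subjects)),
            !anyDuplicated(subjects$subject_id),
            test_fraction > 0, test_fraction < 1, n_folds >= 2)
  groups <- unique(subjects$group)
  res <- with_seed(as.integer(seed), {
    test <- character(0)
    for (g in groups) {
      ids <- sample(subjects$subject_id[subjects$group == g])
      n_test <- floor(length(ids) * test_fraction + 0.5 - 1e-9)  # ties -> train
      test <- c(test, ids[seq_len(n_test)])
    }
    train <- setdiff(subjects$subject_id, test)
    for (g in groups) {
      gi <- subjects$group[match(c(train, test), subjects$subject_id)]
      if (!g %in% gi[seq_along(train)] || !g %in% gi[-seq_along(train)])
        stop("group ", g, " absent from train or test: too few subjects ",
             "for a stratified split")
    }
    if (length(train) < n_folds)
      stop(length(train), " training subjects cannot fill ", n_folds,
           " folds")
    folds <- rep(list(character(0)), n_folds)
    slot <- 0L
    for (g in groups) {                       # round-robin per group
      for (id in sample(train[subjects$group[match(train, subjects$subject_id)] == g])) {
        slot <- slot %% n_folds + 1L
        folds[[slot]] <- c(folds[[slot]], id)
      }
    }
    list(train = sort(train), test = sort(test), folds = folds)
  })
  structure(list(train_subjects = res$train, test_subjects = res$test,
                 folds = res$folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan (seed %d): %d train / %d test subjects, %d folds\n",
              x$seed, length(x$train_subjects), length(x$test_subjects),
              length(x$folds)))
  invisible(x)
}

#' Serialize a split plan to JSON
#' @param plan A [make_split()] plan.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(seed = plan$seed, train_subjects = plan$train_subjects,
         test_subjects = plan$test_subjects, folds = plan$folds),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Restrict a feature table to one binary task
#'
#' Keeps the rows of the task's two groups and attaches a binary `label`
#' column with the disease group as the positive class (AD positive in
#' AD-vs-FTD).
#'
#' @param features Feature data.frame with a `group` column.
#' @param task One of `"AD-vs-HC"`, `"FTD-vs-HC"`, `"AD-vs-FTD"`.
#' @return Filtered data.frame with integer `label` (1 = positive class).
#' @export
assemble_task <- function(features, task = c("AD-vs-HC", "FTD-vs-HC", "AD-vs-FTD")) {
  task <- match.arg(task)
  parts <- strsplit(task, "-vs-")[[1]]
  pos <- parts[1]; neg <- parts[2]
  for (g in parts)
    if (!g %in% features$group)
      stop("group ", g, " missing from feature table for task ", task)
  out <- features[features$group %in% parts, , drop = FALSE]
  out$label <- as.integer(out$group == pos)
  attr(out, "task") <- task
  attr(out, "positive") <- pos
  rownames(out) <- NULL
  out
}

#' SMOTE oversampling of the minority class
#'
#' For each synthetic row needed to balance the two classes, picks a random
#' minority row, one of its `k_neighbors` nearest minority neighbours
#' (Euclidean distance over the feature columns), and emits the convex
#' combination `x + u * (xn - x)` with `u ~ Uniform(0, 1)`. Synthetic rows
#' are flagged (`.synthetic = TRUE`) and given the sentinel subject id
#' `"SMOTE"` so they can never reach a test set. Already-balanced input is
#' returned unchanged.
#'
#' @param features Labelled feature data.frame (training rows only; see
#'   `label` from [assemble_task()]).
#' @param k_neighbors Number of nearest neighbours to interpolate with
#'   (default 5).
#' @param seed Integer seed.
#' @return The input rows plus synthetic minority rows; classes balanced.
#' @export
smote_oversample <- function(features, k_neighbors = 5, seed = 1) {
  stopifnot("label" %in% names(features), k_neighbors >= 1)
  counts <- table(features$label)
  if (length(counts) != 2) stop("SMOTE requires exactly two classes, got ",
                                length(counts))
  if (counts[1] == counts[2]) return(features)
  minority <- names(counts)[which.min(counts)]
  need <- abs(diff(as.integer(counts)))
  cols <- feature_cols(features)
  Xm <- as.matrix(features[features$label == as.integer(minority), cols,
                           drop = FALSE])
  nm <- nrow(Xm)
  if (nm <= k_neighbors)
    stop("minority class has ", nm, " rows; needs more than k_neighbors = ",
         k_neighbors)
  # chunked neighbour search keeps memory bounded for large window counts
  nn <- matrix(0L, nm, k_neighbors)
  sq <- rowSums(Xm^2)
  chunk <- max(1L, floor(2e6 / nm))
  for (s in seq(1, nm, by = chunk)) {
    idx <- s:min(s + chunk - 1, nm)
    D <- outer(sq[idx], sq, "+") - 2 * tcrossprod(Xm[idx, , drop = FALSE], Xm)
    D[cbind(seq_along(idx), idx)] <- Inf
    nn[idx, ] <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
  }
  syn <- with_seed(as.integer(seed), {
    base_i <- sample.int(nm, need, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample.int(k_neighbors, need, replace = TRUE))]
    u <- stats::runif(need)
    Xm[base_i, , drop = FALSE] +
      u * (Xm[nb_i, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  if (!".synthetic" %in% names(features)) features$.synthetic <- FALSE
  synth <- features[rep(1, need), , drop = FALSE]
  synth[, cols] <- syn
  synth$subject_id <- "SMOTE"
  synth$group <- features$group[features$label == as.integer(minority)][1]
  synth$window_index <- NA_integer_
  synth$label <- as.integer(minority)
  synth$.synthetic <- TRUE
  out <- rbind(features, synth)
  rownames(out) <- NULL
  for (a in c("task", "positive", "measure"))
    attr(out, a) <- attr(features, a)
  out
}
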
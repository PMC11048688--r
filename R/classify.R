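# The four finalist learners (KNN, Random Forest, XGBoost, Extra Trees) with
# the study's fixed hyperparameters, plus the confusion-matrix metric suite
# and the task runners. KNN and all metrics are implemented natively; the
# tree ensembles are backed by ranger and xgboost configured to match.

default_hyperparameters <- function(learner) {
  switch(learner,
    KNN = list(n_neighbors = 6, metric = "euclidean", weights = "uniform",
               leaf_size = 30, p = 2),
    RF  = list(criterion = "gini", n_estimators = 120, max_depth = NULL,
               min_samples_split = 28, min_samples_leaf = 10),
    XGB = list(learning_rate = 0.1, n_estimators = 280, max_depth = 8,
               colsample_bytree = 1, reg_alpha = 0.05),
    ET  = list(criterion = "gini", n_estimators = 150, max_depth = NULL,
               min_samples_split = 30, min_samples_leaf = 15),
    stop("unknown learner: ", learner))
}

#' Classifier specification
#'
#' One of the four finalist learners with its tuned hyperparameters. The
#' defaults are the fixed configurations used throughout the study; override
#' entries via `hyperparameters`.
#'
#' @param learner `"KNN"`, `"RF"`, `"XGB"` or `"ET"`.
#' @param hyperparameters Named list overriding individual defaults.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(learner = c("KNN", "RF", "XGB", "ET"),
                            hyperparameters = NULL) {
  learner <- match.arg(learner)
  hp <- default_hyperparameters(learner)
  for (nm in names(hyperparameters)) hp[[nm]] <- hyperparameters[[nm]]
  structure(list(learner = learner, hyperparameters = hp),
            class = "classifier_spec")
}

#' Train a binary classifier on labelled feature rows
#'
#' Fits the specified learner on the feature columns of `train_rows` with
#' `label` as the binary target (1 = positive class). Tree ensembles expose
#' impurity importances; every learner returns a positive-class score.
#' Deterministic under `seed`.
#'
#' @param spec A [classifier_spec()].
#' @param train_rows Labelled feature data.frame (see [assemble_task()]).
#' @param seed Integer seed.
#' @return Object of class `eeg_classifier` with a [predict][predict.eeg_classifier] method.
#' @export
train_classifier <- function(spec, train_rows, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"), "label" %in% names(train_rows))
  cols <- feature_cols(train_rows)
  X <- as.matrix(train_rows[, cols, drop = FALSE])
  y <- as.integer(train_rows$label)
  if (length(unique(y)) < 2) stop("training data contains a single class")
  if (any(table(y) < 2)) stop("need at least 2 rows per class")
  hp <- spec$hyperparameters
  fit <- switch(spec$learner,
    KNN = list(X = X, y = y, k = hp$n_neighbors),
    RF = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$n_estimators, splitrule = hp$criterion,
      min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
      importance = "impurity", seed = seed, num.threads = 1),
    ET = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$n_estimators, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
      importance = "impurity", seed = seed, num.threads = 1),
    XGB = with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$learning_rate,
                    max_depth = hp$max_depth,
                    colsample_bytree = hp$colsample_bytree,
                    alpha = hp$reg_alpha, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = hp$n_estimators, verbose = 0)))
  structure(list(learner = spec$learner, fit = fit, features = cols,
                 seed = seed),
            class = "eeg_classifier")
}

# KNN scores: fraction of the k nearest training rows that are positive;
# 3-3 label ties are broken toward the class of the single nearest
# neighbour. Chunked distance computation bounds memory.
knn_predict <- function(fit, newX) {
  n <- nrow(newX)
  k <- fit$k
  sqtr <- rowSums(fit$X^2)
  score <- numeric(n)
  label <- integer(n)
  chunk <- max(1L, floor(4e6 / nrow(fit$X)))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    D <- outer(rowSums(newX[idx, , drop = FALSE]^2), sqtr, "+") -
      2 * tcrossprod(newX[idx, , drop = FALSE], fit$X)
    for (j in seq_along(idx)) {
      nb <- order(D[j, ])[seq_len(k)]
      votes <- fit$y[nb]
      score[idx[j]] <- mean(votes)
      label[idx[j]] <- if (sum(votes) * 2 == k) votes[1]
                       else as.integer(sum(votes) * 2 > k)
    }
  }
  list(label = label, score = score)
}

#' Predict labels and positive-class scores
#'
#' @param object An [train_classifier()] model.
#' @param newdata Feature data.frame or matrix with the training columns.
#' @param ... Unused.
#' @return List with integer `label` and numeric `score` (positive-class
#'   probability or vote fraction).
#' @export
predict.eeg_classifier <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  switch(object$learner,
    KNN = knn_predict(object$fit, X),
    RF = ,
    ET = {
      p <- stats::predict(object$fit, data = X, num.threads = 1)$predictions[, "1"]
      list(label = as.integer(p >= 0.5), score = p)
    },
    XGB = {
      p <- stats::predict(object$fit, X)
      list(label = as.integer(p >= 0.5), score = p)
    })
}

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary vectors (1 = positive).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Metric suite from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/total`, and F1 as the harmonic mean of precision and
#' sensitivity. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param cc A [confusion()] object or list with `TP`, `FP`, `TN`, `FN`.
#' @return Named list: `sensitivity`, `precision`, `accuracy`, `f1`.
#' @export
classification_metrics <- function(cc) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(cc$TP, cc$TP + cc$FN)
  prec <- rate(cc$TP, cc$TP + cc$FP)
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, precision = prec,
       accuracy = rate(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN),
       f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outranks
#' a random negative, with midpoint handling of score ties — identical to
#' the area traced by the ROC curve over all thresholds.
#'
#' @param y_true Binary truth vector.
#' @param scores Positive-class scores.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)          # average ranks handle ties at the midpoint
  (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Run one classification task end-to-end
#'
#' Filters the feature table to the task, applies the subject-disjoint
#' split, optionally runs subject-wise cross-validation over the plan's
#' folds (SMOTE re-applied inside each fold's training part), then trains on
#' the SMOTE-balanced full training rows and evaluates on the untouched test
#' windows.
#'
#' @param features Feature data.frame from [cohort_feature_table()].
#' @param task Task name, see [assemble_task()].
#' @param spec A [classifier_spec()].
#' @param plan A [make_split()] plan.
#' @param seed Integer seed for SMOTE and learner randomness.
#' @param cv Run per-fold cross-validation (default TRUE).
#' @param smote_k SMOTE neighbour count (default 5).
#' @return Object of class `eeg_eval`: per-fold CV metrics, their means,
#'   test-set metrics (overall and per class), and test window counts per
#'   class.
#' @export
run_task <- function(features, task, spec, plan, seed = 1, cv = TRUE,
                     smote_k = 5) {
  tab <- assemble_task(features, task)
  tab <- tab[tab$subject_id != "SMOTE", , drop = FALSE]
  train <- tab[tab$subject_id %in% plan$train_subjects, , drop = FALSE]
  test <- tab[tab$subject_id %in% plan$test_subjects, , drop = FALSE]
  if (length(intersect(unique(train$subject_id), unique(test$subject_id))))
    stop("split plan leaks subjects between train and test")
  if (nrow(train) == 0 || nrow(test) == 0)
    stop("task ", task, " has empty train or test rows under this plan")

  eval_fold <- function(tr, va, fold_seed) {
    tr <- smote_safe(tr, smote_k, fold_seed)
    model <- train_classifier(spec, tr, seed = fold_seed)
    pr <- predict(model, va)
    m <- classification_metrics(confusion(va$label, pr$label))
    m$auc <- auc(va$label, pr$score)
    m
  }

  cv_tab <- NULL
  if (cv) {
    rows <- lapply(seq_along(plan$folds), function(f) {
      hold <- plan$folds[[f]]
      tr <- train[!train$subject_id %in% hold, , drop = FALSE]
      va <- train[train$subject_id %in% hold, , drop = FALSE]
      if (nrow(va) == 0 || length(unique(tr$label)) < 2)
        return(data.frame(fold = f, sensitivity = NA, precision = NA,
                          accuracy = NA, f1 = NA, auc = NA))
      m <- eval_fold(tr, va, seed + f)
      data.frame(fold = f, sensitivity = m$sensitivity, precision = m$precision,
                 accuracy = m$accuracy, f1 = m$f1, auc = m$auc)
    })
    cv_tab <- do.call(rbind, rows)
  }

  train_bal <- smote_safe(train, smote_k, seed)
  model <- train_classifier(spec, train_bal, seed = seed)
  pr <- predict(model, test)
  cc <- confusion(test$label, pr$label)
  m <- classification_metrics(cc)
  m$auc <- auc(test$label, pr$score)
  per_class <- lapply(c(positive = 1, negative = 0), function(cls) {
    yt <- as.integer(test$label == cls)
    yp <- as.integer(pr$label == cls)
    c(classification_metrics(confusion(yt, yp)), n_windows = sum(yt))
  })
  structure(list(task = task, learner = spec$learner, seed = seed,
                 positive = attr(tab, "positive"),
                 cv = cv_tab,
                 cv_mean = if (!is.null(cv_tab))
                   colMeans(cv_tab[, -1], na.rm = TRUE),
                 test = c(m, list(confusion = cc)),
                 test_per_class = per_class,
                 model = model,
                 n_train_rows = nrow(train_bal), n_test_rows = nrow(test)),
            class = "eeg_eval")
}

# SMOTE that passes balanced input through and tolerates tiny minorities by
# shrinking k.
smote_safe <- function(tr, k, seed) {
  counts <- table(tr$label)
  if (length(counts) == 2 && counts[1] != counts[2]) {
    k_eff <- min(k, min(counts) - 1)
    if (k_eff >= 1) tr <- smote_oversample(tr, k_neighbors = k_eff,
                                           seed = seed)
  }
  tr
}

#' @export
print.eeg_eval <- function(x, ...) {
  cat(sprintf("Task %s | %s (positive = %s)\n", x$task, x$learner, x$positive))
  if (!is.null(x$cv_mean))
    cat(sprintf("  CV mean (%d folds): acc %.3f  prec %.3f  sens %.3f  F1 %.3f  AUC %.3f\n",
                nrow(x$cv), x$cv_mean[["accuracy"]], x$cv_mean[["precision"]],
                x$cv_mean[["sensitivity"]], x$cv_mean[["f1"]],
                x$cv_mean[["auc"]]))
  t <- x$test
  cat(sprintf("  Test (%d windows): acc %.3f  prec %.3f  sens %.3f  F1 %.3f  AUC %.3f\n",
              x$n_test_rows, t$accuracy, t$precision, t$sensitivity, t$f1,
              t$auc))
  invisible(x)
}

#' Run the full evaluation grid
#'
#' Evaluates every combination of overlap, feature measure, learner and task
#' over several split seeds, reporting the mean and standard deviation of
#' the test metrics per cell. Feature tables are computed once per
#' (measure, overlap) pair and reused across seeds.
#'
#' @param cohort List of [eeg_recording()]s.
#' @param overlaps Overlap fractions (default `c(0.5, 0.9)`).
#' @param measures Feature measures (default all five).
#' @param learners Learner names (default all four).
#' @param tasks Task names (default all three).
#' @param seeds Split seeds (default `1:5`).
#' @param cv Run CV inside each cell (default FALSE; the per-cell summary
#'   uses test metrics).
#' @param n_folds CV folds when `cv = TRUE`.
#' @return data.frame grid with one row per cell: mean and sd of accuracy,
#'   precision, sensitivity, F1 and AUC over seeds.
#' @export
run_matrix <- function(cohort, overlaps = c(0.5, 0.9),
                       measures = feature_measures,
                       learners = c("KNN", "RF", "XGB", "ET"),
                       tasks = c("AD-vs-HC", "FTD-vs-HC", "AD-vs-FTD"),
                       seeds = 1:5, cv = FALSE, n_folds = 15) {
  measures <- match.arg(measures, feature_measures, several.ok = TRUE)
  subjects <- data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, ""),
    group = vapply(cohort, function(r) r$group, ""), stringsAsFactors = FALSE)
  plans <- lapply(seeds, function(s)
    make_split(subjects, n_folds = n_folds, seed = s))
  grid <- list()
  for (ov in overlaps) {
    for (ms in measures) {
      feats <- cohort_feature_table(cohort, window_spec(1, ov), ms)
      for (ln in learners) {
        for (tk in tasks) {
          vals <- lapply(seq_along(seeds), function(i) {
            ev <- run_task(feats, tk, classifier_spec(ln), plans[[i]],
                           seed = seeds[i], cv = cv)
            unlist(ev$test[c("accuracy", "precision", "sensitivity", "f1",
                             "auc")])
          })
          V <- do.call(rbind, vals)
          grid[[length(grid) + 1L]] <- data.frame(
            overlap = ov, measure = ms, learner = ln, task = tk,
            n_seeds = length(seeds),
            t(c(colMeans(V, na.rm = TRUE),
                stats::setNames(apply(V, 2, stats::sd, na.rm = TRUE),
                                paste0(colnames(V), "_sd")))),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, grid)
  rownames(out) <- NULL
  out
}
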
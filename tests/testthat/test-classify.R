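# Learners, metric formulas, AUC, and the task runner's leakage guards.

test_that("KNN separates well-separated blobs perfectly", {
  tab <- blob_table(n_subj = 5, windows = 20, sep = 6, subject_sd = 0.1)
  tab <- assemble_task(tab, "AD-vs-HC")
  plan <- make_split(unique(tab[, c("subject_id", "group")]),
                     n_folds = 4, seed = 2)
  ev <- run_task(tab, "AD-vs-HC", classifier_spec("KNN"), plan,
                 seed = 1, cv = FALSE)
  expect_equal(ev$test$accuracy, 1.0)
})

test_that("all four learners are deterministic under seed", {
  tab <- assemble_task(blob_table(n_subj = 6, windows = 15, sep = 1.2),
                       "AD-vs-HC")
  train <- tab[!tab$subject_id %in% c("AD01", "HC01"), ]
  test <- tab[tab$subject_id %in% c("AD01", "HC01"), ]
  for (ln in c("KNN", "RF", "XGB", "ET")) {
    m1 <- train_classifier(classifier_spec(ln), train, seed = 9)
    m2 <- train_classifier(classifier_spec(ln), train, seed = 9)
    expect_identical(predict(m1, test)$score, predict(m2, test)$score,
                     label = paste(ln, "scores"))
  }
  expect_error(train_classifier(classifier_spec("KNN"),
                                tab[tab$label == 1, ], seed = 1),
               "single class")
})

test_that("confusion counts are exact", {
  y <- c(rep(1, 10), rep(0, 10))
  p <- y; p[10] <- 0; p[20] <- 1
  cc <- confusion(y, p)
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 9, FN = 1, FP = 1, TN = 9))
  perfect <- confusion(y, y)
  expect_equal(perfect$FN + perfect$FP, 0)
  allpos <- confusion(y, rep(1, 20))
  expect_equal(allpos$TN, 0)
  expect_equal(allpos$FP / (allpos$FP + allpos$TN), 1)  # FPR = 1
  expect_error(confusion(y, p[-1]), "length")
})

test_that("metric formulas match direct arithmetic and flag undefined", {
  m <- classification_metrics(list(TP = 9, FN = 1, FP = 2, TN = 8))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  expect_true(is.na(classification_metrics(
    list(TP = 0, FP = 0, TN = 5, FN = 5))$precision))
  # brute-force identity on random counts
  set.seed(8)
  for (i in 1:50) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    if (cc$TP + cc$FN == 0 || cc$TP + cc$FP == 0) next
    m <- classification_metrics(cc)
    P <- cc$TP / (cc$TP + cc$FP); R <- cc$TP / (cc$TP + cc$FN)
    expect_equal(m$accuracy,
                 (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN))
    if (P + R > 0) expect_equal(m$f1, 2 * P * R / (P + R))
  }
})

test_that("auc equals the exhaustive pairwise-ranking oracle", {
  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_true(is.na(auc(c(1, 1), c(0.2, 0.3))))
  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))   # coarse scores force ties
    expect_lt(abs(auc(y, s) - pair_auc(y, s)), 1e-12)
  }
})

test_that("run_task reports 15 folds, per-class counts, and no leakage", {
  tab <- assemble_task(blob_table(n_subj = 10, windows = 12, sep = 1.5),
                       "AD-vs-HC")
  plan <- make_split(unique(tab[, c("subject_id", "group")]),
                     n_folds = 15, seed = 3)
  ev <- run_task(tab, "AD-vs-HC", classifier_spec("KNN"), plan, seed = 3,
                 cv = TRUE)
  expect_equal(nrow(ev$cv), 15)
  counts <- vapply(ev$test_per_class, function(x) x$n_windows, numeric(1))
  test_rows <- tab[tab$subject_id %in% plan$test_subjects, ]
  expect_equal(unname(counts["positive"]), sum(test_rows$label == 1))
  expect_equal(unname(counts["negative"]), sum(test_rows$label == 0))
  expect_equal(sum(counts), ev$n_test_rows)
})

test_that("label permutation at subject level drives accuracy to chance", {
  tab <- blob_table(n_subj = 12, windows = 15, sep = 1.5, seed = 5)
  accs <- numeric(20)
  set.seed(99)
  for (r in 1:20) {
    perm <- tab
    subj <- unique(perm$subject_id)
    newg <- sample(rep(c("AD", "HC"), length.out = length(subj)))
    perm$group <- newg[match(perm$subject_id, subj)]
    ptab <- assemble_task(perm, "AD-vs-HC")
    plan <- make_split(unique(ptab[, c("subject_id", "group")]),
                       n_folds = 4, seed = r)
    ev <- run_task(ptab, "AD-vs-HC", classifier_spec("KNN"), plan,
                   seed = r, cv = FALSE)
    accs[r] <- ev$test$accuracy
  }
  expect_equal(mean(accs), 0.5, tolerance = 0.1 / 0.5)
})

test_that("run_matrix produces the full grid with bounded means", {
  coh <- tiny_cohort(n = 4, duration_s = 6, seed = 31)
  grid <- run_matrix(coh, overlaps = 0.5, measures = c("svd", "zcr"),
                     learners = c("KNN", "XGB"),
                     tasks = c("AD-vs-HC", "AD-vs-FTD"), seeds = 1:2,
                     n_folds = 3)
  expect_equal(nrow(grid), 1 * 2 * 2 * 2)
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  expect_true(all(grid$n_seeds == 2))
})
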
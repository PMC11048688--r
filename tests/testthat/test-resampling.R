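# Subject-disjoint splitting, CV folds, task assembly, and SMOTE.

subjects_df <- function(n_ad = 10, n_hc = 10, n_ftd = 0) {
  data.frame(
    subject_id = c(sprintf("AD%02d", seq_len(n_ad)),
                   sprintf("HC%02d", seq_len(n_hc)),
                   if (n_ftd) sprintf("FTD%02d", seq_len(n_ftd))),
    group = c(rep("AD", n_ad), rep("HC", n_hc), rep("FTD", n_ftd)),
    stringsAsFactors = FALSE)
}

test_that("splits are subject-disjoint, stratified and complete", {
  subj <- subjects_df(10, 10)
  plan <- make_split(subj, test_fraction = 0.2, n_folds = 5, seed = 1)
  expect_length(plan$test_subjects, 4)
  expect_length(plan$train_subjects, 16)
  expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
  expect_setequal(c(plan$train_subjects, plan$test_subjects),
                  subj$subject_id)
  # stratified: two test subjects per group
  expect_equal(sum(grepl("^AD", plan$test_subjects)), 2)
  # folds partition the training subjects
  expect_setequal(unlist(plan$folds), plan$train_subjects)
  expect_equal(anyDuplicated(unlist(plan$folds)), 0)
})

test_that("splits are deterministic per seed and differ across seeds", {
  subj <- subjects_df(30, 30)
  plans <- lapply(1:5, function(s) make_split(subj, n_folds = 15, seed = s))
  tests <- lapply(plans, `[[`, "test_subjects")
  expect_equal(length(unique(tests)), 5)
  for (s in 1:5)
    expect_identical(make_split(subj, n_folds = 15, seed = s)$test_subjects,
                     tests[[s]])
})

test_that("degenerate splits are refused", {
  expect_error(make_split(subjects_df(2, 2), n_folds = 2, seed = 1),
               "absent|folds")
  expect_error(make_split(subjects_df(6, 6), n_folds = 15, seed = 1),
               "folds")
})

test_that("assemble_task filters to the task groups and labels the disease", {
  tab <- blob_table(n_subj = 3, windows = 5, sep = 1,
                    groups = c("AD", "HC"))
  ftd <- blob_table(n_subj = 2, windows = 5, sep = 0, groups = c("FTD"))
  all3 <- rbind(tab, ftd)
  out <- assemble_task(all3, "AD-vs-HC")
  expect_equal(nrow(out), sum(all3$group %in% c("AD", "HC")))
  expect_setequal(unique(out$group), c("AD", "HC"))
  expect_true(all(out$label[out$group == "AD"] == 1))
  expect_true(all(out$label[out$group == "HC"] == 0))
  out2 <- assemble_task(all3, "AD-vs-FTD")
  expect_equal(attr(out2, "positive"), "AD")
  expect_error(assemble_task(tab, "AD-vs-FTD"), "FTD")
})

test_that("SMOTE balances classes with convex synthetic rows", {
  tab <- assemble_task(blob_table(n_subj = 2, windows = 5, sep = 1), "AD-vs-HC")
  minority <- tab[tab$label == 1, ][1:6, ]       # 6 minority rows
  majority <- tab[tab$label == 0, ]              # 10 majority rows
  inp <- rbind(majority, minority)
  out <- smote_oversample(inp, k_neighbors = 5, seed = 3)
  expect_equal(as.vector(table(out$label)), c(10, 10))
  syn <- out[out$.synthetic, ]
  expect_equal(nrow(syn), 4)
  expect_true(all(syn$subject_id == "SMOTE"))
  cols <- eegdem:::feature_cols(inp)
  Xm <- as.matrix(minority[, cols])
  for (i in seq_len(nrow(syn))) {
    v <- as.numeric(syn[i, cols])
    # every coordinate must lie within the minority hull's bounding box,
    # and the row must be on a segment between two minority parents
    expect_true(all(v >= apply(Xm, 2, min) - 1e-9))
    expect_true(all(v <= apply(Xm, 2, max) + 1e-9))
    on_segment <- FALSE
    for (a in seq_len(nrow(Xm) - 1)) for (b in (a + 1):nrow(Xm)) {
      d <- Xm[b, ] - Xm[a, ]
      u <- if (sum(d^2) == 0) 0 else sum((v - Xm[a, ]) * d) / sum(d^2)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((Xm[a, ] + u * d - v)^2)) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
})

test_that("SMOTE is a no-op on balanced input and validates its inputs", {
  tab <- assemble_task(blob_table(n_subj = 2, windows = 5, sep = 1), "AD-vs-HC")
  expect_identical(smote_oversample(tab, seed = 1), tab)
  tiny <- rbind(tab[tab$label == 0, ][1:8, ], tab[tab$label == 1, ][1:3, ])
  expect_error(smote_oversample(tiny, k_neighbors = 5, seed = 1),
               "minority")
  tab3 <- tab; tab3$label[1:3] <- 2
  expect_error(smote_oversample(tab3, seed = 1), "two classes")
})

test_that("SMOTE is deterministic under its seed", {
  tab <- assemble_task(blob_table(n_subj = 3, windows = 7, sep = 1), "AD-vs-HC")
  inp <- rbind(tab[tab$label == 0, ], tab[tab$label == 1, ][1:10, ])
  expect_identical(smote_oversample(inp, seed = 5),
                   smote_oversample(inp, seed = 5))
  expect_false(identical(smote_oversample(inp, seed = 5),
                         smote_oversample(inp, seed = 6)))
})
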
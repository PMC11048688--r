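# Complexity features: analytic limits, independent oracles, invariances,
# and the feature-table contract.

test_that("svd entropy matches its bounds and the constant case", {
  expect_identical(svd_entropy(rep(5, 500)), 0)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(500)
    expect_lte(svd_entropy(x), log2(3) + 1e-12)
  }
  set.seed(2)
  v <- svd_entropy(rnorm(500))
  expect_gt(v, 1.40)
  expect_lt(v, log2(3))
  expect_error(svd_entropy(c(1, NA, 3, 4)), "finite")
})

test_that("svd entropy agrees with an independent SVD-based oracle", {
  oracle <- function(x, order) {
    s <- svd(stats::embed(x, order))$d       # LAPACK SVD on embed()'s matrix
    p <- s / sum(s)
    p <- p[p > 1e-15]
    -sum(p * log2(p))
  }
  set.seed(10)
  for (i in 1:100) {
    n <- sample(50:500, 1)
    ord <- sample(2:5, 1)
    x <- switch(sample(3, 1), rnorm(n), cumsum(rnorm(n)),
                sin(seq(0, 20, length.out = n)) + rnorm(n, 0, 0.3))
    expect_lt(abs(svd_entropy(x, order = ord) - oracle(x, ord)), 1e-6)
  }
})

test_that("higuchi dimension recovers known fractal classes", {
  expect_equal(higuchi_fd(0.01 * (1:500)), 1, tolerance = 0.02)
  expect_identical(higuchi_fd(rep(2, 500)), 1)
  white <- vapply(1:50, function(i) { set.seed(i); higuchi_fd(rnorm(500)) },
                  numeric(1))
  brown <- vapply(1:50, function(i) { set.seed(i)
    higuchi_fd(cumsum(rnorm(500))) }, numeric(1))
  expect_equal(mean(white), 2, tolerance = 0.15 / 2)
  expect_equal(mean(brown), 1.5, tolerance = 0.15 / 1.5)
})

test_that("zero crossing rate counts strict sign changes", {
  expect_identical(zero_crossing_rate(rep(3, 500)), 0)
  expect_identical(zero_crossing_rate(rep(c(1, -1), 250)), 1)
  x <- sin(2 * pi * 10 * (1:500) / 500 + 0.1)
  expect_identical(zero_crossing_rate(x), 20 / 499)
  # direct recount as oracle
  expect_identical(zero_crossing_rate(x),
                   sum(x[-1] * x[-length(x)] < 0) / (length(x) - 1))
  # exact zeros break crossings (strict < 0)
  expect_identical(zero_crossing_rate(c(1, 0, -1, 0, 1)), 0)
  expect_error(zero_crossing_rate(1))
})

test_that("dfa recovers known scaling exponents", {
  white <- vapply(1:50, function(i) { set.seed(i); dfa(rnorm(2000)) },
                  numeric(1))
  brown <- vapply(1:50, function(i) { set.seed(i); dfa(cumsum(rnorm(2000))) },
                  numeric(1))
  expect_equal(mean(white), 0.5, tolerance = 0.1 / 0.5)
  expect_equal(mean(brown), 1.5, tolerance = 0.15 / 1.5)
})

test_that("dfa flags degenerate signals naming the scale", {
  # constant input -> zero profile -> F(n) = 0 at the smallest scale
  expect_error(dfa(rep(3, 256)), "scale n = 4")
})

test_that("features are gain-invariant except Hjorth activity", {
  set.seed(3)
  c_ <- 7.3
  for (i in 1:10) {
    x <- cumsum(rnorm(400))
    expect_equal(svd_entropy(c_ * x), svd_entropy(x), tolerance = 1e-10)
    expect_equal(higuchi_fd(c_ * x), higuchi_fd(x), tolerance = 1e-10)
    expect_equal(dfa(c_ * x), dfa(x), tolerance = 1e-10)
    expect_equal(zero_crossing_rate(c_ * x), zero_crossing_rate(x))
    h1 <- hjorth(x); h2 <- hjorth(c_ * x)
    expect_equal(h2$mobility, h1$mobility, tolerance = 1e-12)
    expect_equal(h2$complexity, h1$complexity, tolerance = 1e-12)
    expect_equal(h2$activity, c_^2 * h1$activity, tolerance = 1e-12)
  }
})

test_that("hjorth parameters match their definitions", {
  t <- 1:500
  s <- 2 * sin(2 * pi * 10 * t / 500)
  expect_equal(hjorth(s)$activity, 2, tolerance = 0.05 / 2)
  mob <- vapply(1:50, function(i) { set.seed(i); hjorth(rnorm(2000))$mobility },
                numeric(1))
  expect_equal(mean(mob), sqrt(2), tolerance = 0.05 / sqrt(2))
  expect_error(hjorth(rep(1, 100)), "constant")
  # scalar summary is the mean of mobility and complexity
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(300)
    h <- hjorth(x)
    expect_equal(hjorth_scalar(x), (h$mobility + h$complexity) / 2)
  }
})

test_that("feature table has the contracted shape and per-cell values", {
  ws <- manual_window_set(21, 19, 100)
  tab <- extract_feature_table(ws, "svd")
  expect_equal(dim(tab), c(21, 22))
  expect_equal(colnames(tab)[1:3], c("subject_id", "group", "window_index"))
  expect_equal(colnames(tab)[-(1:3)], montage_1020()$channel)
  # exhaustive per-cell equality on a small fixture
  small <- manual_window_set(3, 19, 80)
  for (m in c("svd", "zcr", "hjorth")) {
    tb <- extract_feature_table(small, m)
    f <- eegdem:::feature_fun(m)
    for (i in 1:3) for (ch in 1:19)
      expect_equal(tb[i, 3 + ch], f(small$windows[i, ch, ]))
  }
})

test_that("empty window sets and failing windows are handled", {
  empty <- manual_window_set(0, 19, 100)
  tab <- extract_feature_table(empty, "svd")
  expect_equal(nrow(tab), 0)
  # a constant channel kills hjorth for that window only
  ws <- manual_window_set(4, 19, 100)
  ws$windows[2, 5, ] <- 3
  expect_message(tab <- extract_feature_table(ws, "hjorth"), "1 window")
  expect_equal(nrow(tab), 3)
  expect_false(1L %in% tab$window_index)
  expect_error(extract_feature_table(ws, "nope"))
})

test_that("svd entropy separates the synthetic classes at the group level", {
  coh <- tiny_cohort(n = 10, duration_s = 6, seed = 21)
  tab <- cohort_feature_table(coh, window_spec(1, 0.5), "svd")
  subj <- aggregate(rowMeans(tab[, eegdem:::feature_cols(tab)]),
                    list(subject = tab$subject_id, group = tab$group), mean)
  ad <- subj$x[subj$group == "AD"]; hc <- subj$x[subj$group == "HC"]
  se <- sqrt(var(ad) / length(ad) + var(hc) / length(hc))
  expect_gt(abs(mean(ad) - mean(hc)), se)
})
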
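test_that("confusion metrics are exact on canonical cases", {
  perfect <- confusion_metrics(50, 50, 0, 0)
  expect_equal(unlist(perfect[, .(mcc, accuracy, f1, fowlkes_mallows,
                                  sensitivity, specificity)]),
               c(mcc = 1, accuracy = 1, f1 = 1, fowlkes_mallows = 1,
                 sensitivity = 1, specificity = 1))

  degenerate <- confusion_metrics(0, 100, 0, 0)
  expect_equal(degenerate$mcc, 0)
  expect_true(degenerate$mcc_zero_denom)
  expect_equal(degenerate$specificity, 1)

  expect_error(confusion_metrics(0, 0, 0, 0), "all-zero")
  expect_error(confusion_metrics(-1, 1, 1, 1), "nonnegative")
})

test_that("metric formulas agree with direct arithmetic on a small grid", {
  g <- expand.grid(tp = 0:6, tn = 0:6, fp = 0:6, fn = 0:6)
  g <- g[rowSums(g) > 0, ]
  got <- confusion_metrics(g$tp, g$tn, g$fp, g$fn)
  with(g, {
    expect_equal(got$accuracy, (tp + tn) / (tp + tn + fp + fn))
    d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    ok <- d > 0
    expect_equal(got$mcc[ok], ((tp * tn - fp * fn) / d)[ok])
    expect_equal(got$mcc[!ok], rep(0, sum(!ok)))
    ok <- 2 * tp + fp + fn > 0
    expect_equal(got$f1[ok], (2 * tp / (2 * tp + fp + fn))[ok])
    ok <- tp + fp > 0 & tp + fn > 0
    expect_equal(got$fowlkes_mallows[ok],
                 sqrt(tp / (tp + fp) * tp / (tp + fn))[ok])
  })
})

test_that("F1 equals Fowlkes-Mallows when fp == fn", {
  set.seed(53)
  tp <- sample(1:50, 20, replace = TRUE)
  tn <- sample(0:50, 20, replace = TRUE)
  e <- sample(0:20, 20, replace = TRUE)
  m <- confusion_metrics(tp, tn, e, e)
  expect_equal(m$f1, m$fowlkes_mallows)
})

test_that("rank AUC handles separation, ties and matches the pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  set.seed(59)
  for (trial in 1:20) {
    s <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # ties likely
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
  }
})

test_that("rank AUC is invariant under strictly monotone score transforms", {
  set.seed(61)
  s <- rnorm(80); y <- rbinom(80, 1, 0.4)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)
  expect_equal(roc_auc(qlogis(plogis(s)), y), a)
  expect_equal(roc_auc(rank(s), y), a)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(67)
  s <- rnorm(100); y <- rbinom(100, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("leakage filter drops training CNVs near validation CNVs", {
  train <- cnv_records("1", c(1000, 50000, 100000),
                       c(2000, 60000, 101000), "loss",
                       id = c("dup", "near", "far"))
  valid <- cnv_records("1", c(1000, 50000), c(2000, 70500), "loss")
  # "dup" identical (RO 1); "near" RO 10001/20501 < 0.5 retained
  expect_lt(reciprocal_overlap(train[2, ], valid[2, ]), 0.5)
  kept <- suppressMessages(leakage_filter(train, valid))
  expect_equal(kept$id, c("near", "far"))
  expect_equal(attr(kept, "n_dropped"), 1L)
  # empty validation set leaves training untouched
  kept2 <- suppressMessages(leakage_filter(train, valid[0, ]))
  expect_equal(nrow(kept2), 3L)
})

test_that("leakage-filtered output shares no high-RO pair with validation", {
  set.seed(71)
  train <- cnv_records("1", s <- sample(1e6, 60), s + sample(1e3:1e4, 60),
                       "loss", id = sprintf("t%02d", 1:60))
  valid <- cnv_records("1", v <- sample(1e6, 30), v + sample(1e3:1e4, 30),
                       "loss", id = sprintf("v%02d", 1:30))
  kept <- suppressMessages(leakage_filter(train, valid, 0.5))
  for (i in seq_len(nrow(kept))) {
    ro <- reciprocal_overlap(kept[rep(i, nrow(valid)), ], valid)
    expect_true(all(ro < 0.5))
  }
})

test_that("stratified reports tile length bins and pool back to 'all'", {
  set.seed(73)
  lens <- c(rep(5000, 10), rep(50000, 10), rep(5e5, 10), rep(5e6, 10))
  x <- cnv_records("1", seq_along(lens) * 1e7, seq_along(lens) * 1e7 + lens - 1,
                   rep(c("gain", "loss"), 20), id = sprintf("s%02d", 1:40))
  truth <- rbinom(40, 1, 0.5); pred <- ifelse(runif(40) < 0.8, truth, 1 - truth)
  rep_dt <- stratified_report(x, pred, truth)
  expect_equal(rep_dt$stratum,
               c("all", "0-10kb", "10kb-100kb", "100kb-1Mb", "1Mb-10Mb",
                 "gain", "loss"))
  all_row <- rep_dt[rep_dt$stratum == "all", ]
  gl <- rep_dt[rep_dt$stratum %in% c("gain", "loss"), ]
  for (cc in c("tp", "tn", "fp", "fn"))
    expect_equal(sum(gl[[cc]]), all_row[[cc]])
  bins <- rep_dt[!rep_dt$stratum %in% c("all", "gain", "loss"), ]
  expect_equal(sum(bins$n), 40L)

  # boundary membership: 9,999 bp and 10,001 bp fall in different bins
  y <- cnv_records("1", c(1, 1e6), c(9999, 1e6 + 10000), "loss",
                   id = c("a", "b"))
  r2 <- stratified_report(y, c(1, 1), c(1, 1))
  expect_equal(r2[r2$stratum == "0-10kb", ]$n, 1L)
  expect_equal(r2[r2$stratum == "10kb-100kb", ]$n, 1L)

  # all CNVs in one bin: the others are flagged empty
  z <- cnv_records("1", c(1, 1e6), c(5000, 1e6 + 4999), "gain", id = c("a", "b"))
  r3 <- stratified_report(z, c(1, 0), c(1, 0))
  expect_true(r3[r3$stratum == "loss", ]$empty)
  expect_equal(r3[r3$stratum == "0-10kb", ]$n, 2L)
})

test_that("relative improvement reproduces simple arithmetic", {
  expect_equal(round(relative_improvement(0.65, 0.27), 1), 140.7)
  expect_equal(relative_improvement(0.65, -0.08), 912.5)
  expect_equal(relative_improvement(0.4, 0.4), 0)
  expect_error(relative_improvement(0.5, 0), "undefined")
})

test_that("five-tier labels collapse to binary with uncertain excluded", {
  lab <- c("pathogenic", "likely_pathogenic", "uncertain", "likely_benign",
           "benign")
  expect_equal(collapse_labels(lab), c(1L, 1L, NA, 0L, 0L))
})
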
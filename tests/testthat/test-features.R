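test_that("positional aggregation is the mean over covered positions", {
  cnv <- cnv_records("1", 1, 1000, "loss")
  tr <- data.frame(chrom = "1", pos = c(100, 200, 5000), score = c(2, 4, 99))
  expect_equal(aggregate_positional(cnv, tr), 3)           # (2+4)/2
  expect_equal(aggregate_positional(cnv, tr, "total"), 6 / 1000)
  # single covered position returns its value
  expect_equal(aggregate_positional(cnv, data.frame(chrom = "1", pos = 7,
                                                    score = 1.5)), 1.5)
  # no covered position -> missing
  expect_true(is.na(aggregate_positional(cnv, data.frame(chrom = "2", pos = 1,
                                                         score = 1))))
})

test_that("positional aggregation equals a per-base loop on a dense track", {
  set.seed(23)
  track <- data.frame(chrom = "1", pos = 1:500, score = rnorm(500))
  cnvs <- cnv_records("1", c(10, 200, 450), c(60, 390, 600), "loss",
                      id = c("a", "b", "c"))
  got <- aggregate_positional(cnvs, track)
  for (i in 1:3) {
    inside <- track$pos >= cnvs$start[i] & track$pos <= cnvs$end[i]
    expect_equal(got[i], sum(track$score[inside]) / sum(inside))
  }
})

test_that("gene scores reduce by the requested mode", {
  cnv <- cnv_records("1", 1, 10000, "loss")
  tbl <- data.frame(chrom = "1", start = c(100, 5000), end = c(500, 6000),
                    gene = c("g1", "g2"), score = c(0.1, 0.99))
  expect_equal(gene_score(cnv, tbl, "max"), 0.99)
  expect_equal(gene_score(cnv, tbl, "mean"), mean(c(0.1, 0.99)))
  one <- tbl[1, ]; one$score <- 0.5
  expect_equal(gene_score(cnv, one, "max"), 0.5)
  expect_equal(gene_score(cnv, one, "mean"), 0.5)
  expect_true(is.na(gene_score(cnv, data.frame(chrom = "2", start = 1, end = 2,
                                               gene = "g", score = 1))))
})

test_that("regulatory overlap fraction is covered bp over CNV length", {
  cnv <- cnv_records("1", 1, 1000, "loss")
  rs <- data.frame(chrom = "1", start = 101, end = 350)  # 250 bp inside
  expect_equal(region_fraction(cnv, rs), 0.25)
  expect_equal(region_fraction(cnv, data.frame(chrom = "2", start = 1,
                                               end = 10)), 0)
  # length-ratio mode: CNV length over overlapping regulatory length
  rs500 <- data.frame(chrom = "1", start = 301, end = 800)
  expect_equal(region_fraction(cnv, rs500, "length_ratio"), 1000 / 500)
})

test_that("region scores are bounded and invariant to interval splitting", {
  set.seed(31)
  cnvs <- cnv_records("1", c(1, 2001), c(2000, 6000), "loss", id = c("a", "b"))
  whole <- data.frame(chrom = "1", start = c(100, 2500), end = c(900, 4000))
  split2 <- data.frame(chrom = "1", start = c(100, 401, 2500, 3001),
                       end = c(400, 900, 3000, 4000))
  overl <- data.frame(chrom = "1", start = c(100, 300, 2500, 2600),
                      end = c(700, 900, 3500, 4000))
  f_whole <- region_fraction(cnvs, whole)
  expect_true(all(f_whole >= 0 & f_whole <= 1))
  expect_equal(region_fraction(cnvs, split2), f_whole)
  expect_equal(region_fraction(cnvs, overl), f_whole)
})

test_that("CDTS feature is the covered fraction below the percentile threshold", {
  cnv <- cnv_records("1", 1, 100, "loss")
  thr <- c(pct1 = -2, pct5 = -1)
  all_low <- data.frame(chrom = "1", pos = 1:5, score = rep(-3, 5))
  none_low <- data.frame(chrom = "1", pos = 1:5, score = rep(0, 5))
  expect_equal(cdts_feature(cnv, all_low, 1, thr), 1)
  expect_equal(cdts_feature(cnv, none_low, 1, thr), 0)
  # 3 of 10 below the 5% threshold (brute-force count oracle)
  mix <- data.frame(chrom = "1", pos = 1:10,
                    score = c(-1.5, -2, -9, rep(0.5, 7)))
  expect_equal(cdts_feature(cnv, mix, 5, thr), sum(mix$score < -1) / 10)
  expect_error(cdts_feature(cnv, mix, 10, thr), "percentile")
  expect_true(is.na(cdts_feature(cnv, data.frame(chrom = "2", pos = 1,
                                                 score = 0), 1, thr)))
})

test_that("universal features encode type and split PAF by type", {
  db <- af_database(data.frame(chrom = "1", start = 1, end = 10000,
                               cnv_type = "loss", af_overall = 0.02))
  loss <- cnv_records("1", 1, 10000, "loss")
  gain <- cnv_records("1", 1, 10000, "gain")
  u <- universal_features(loss, db)
  expect_equal(unlist(u), c(cnv_length = 10000, cnv_type_gain = 0,
                            paf_gain = 0, paf_loss = 0.02))
  ug <- universal_features(gain, db)  # no gain entry in db
  expect_equal(unlist(ug), c(cnv_length = 10000, cnv_type_gain = 1,
                             paf_gain = 0, paf_loss = 0))
  expect_false(identical(u, ug))
})

test_that("minimum imputation uses training minima and is idempotent", {
  m <- matrix(c(0.2, NA, 0.5, 1, 2, 3), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  mi <- impute_missing(m)
  expect_equal(mi[, "f1"], c(a = 0.2, b = 0.2, c = 0.5))
  expect_true(all(is.finite(mi)))
  expect_equal(impute_missing(mi), mi, ignore_attr = TRUE)  # idempotent
  # fully observed matrix unchanged
  expect_equal(unclass(impute_missing(m[, "f2", drop = FALSE]))[, 1],
               m[, "f2"], ignore_attr = TRUE)
  # predict-time cells take the training minimum, not the batch minimum
  train <- matrix(c(5, 7), ncol = 1, dimnames = list(NULL, "f1"))
  test <- matrix(c(NA, 100), ncol = 1, dimnames = list(NULL, "f1"))
  expect_equal(unname(unclass(impute_missing(test, train))[1, 1]), 5)
  # all-missing training column is a named error
  allna <- matrix(NA_real_, 2, 1, dimnames = list(NULL, "f9"))
  expect_error(impute_missing(allna), "f9")
})

test_that("feature matrix has the fixed 30-column schema", {
  s <- xcnv_feature_schema()
  expect_length(s$all, 30)
  expect_equal(lengths(s[c("universal", "coding", "noncoding", "genomewide")]),
               c(universal = 4, coding = 13, noncoding = 8, genomewide = 5))

  b <- toy_bundle()
  empty <- cnv_records(character(0), numeric(0), numeric(0), character(0))
  m0 <- build_feature_matrix(empty, b)
  expect_equal(dim(m0), c(0L, 30L))
  expect_equal(colnames(m0), s$all)

  x2 <- cnv_records("1", c(100, 100), c(900, 900), "loss", id = c("a", "b"))
  m2 <- build_feature_matrix(x2, b)
  expect_equal(unname(m2["a", ]), unname(m2["b", ]))  # same CNV, same row
  expect_true(is.matrix(attr(m2, "missing")))
})

test_that("bundle validation names the missing annotation source", {
  b <- toy_bundle()
  broken <- b$tracks; broken$CADD <- NULL
  expect_error(xcnv_bundle(broken, b$genes, b$regions, b$cdts_thresholds),
               "CADD")
})

test_that("feature values do not depend on annotation record order", {
  set.seed(37)
  cnvs <- cnv_records("1", c(1000, 4000), c(3000, 9000), "loss",
                      id = c("a", "b"))
  tr <- data.frame(chrom = "1", pos = sample(1000:9000, 40),
                   score = rnorm(40))
  b1 <- toy_bundle(track_vals = list(CADD = tr))
  b2 <- toy_bundle(track_vals = list(CADD = tr[sample(nrow(tr)), ]))
  m1 <- build_feature_matrix(cnvs, b1)
  m2 <- build_feature_matrix(cnvs, b2)
  expect_equal(m1[, "CADD"], m2[, "CADD"])
})
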
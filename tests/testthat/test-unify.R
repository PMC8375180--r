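rec <- function(starts, ends, type = "loss", chrom = "1", ...) {
  cnv_records(chrom, starts, ends, type, ...)
}

test_that("breakpoint distance is the Chebyshev distance on endpoints", {
  a <- rec(1000, 5000)
  expect_equal(cnv_distance(a, rec(1000, 5000)), 0)
  expect_equal(cnv_distance(a, rec(1050, 4980)), 50)
  expect_equal(cnv_distance(a, rec(1200, 5000)), 200)
  expect_equal(cnv_distance(rec(1050, 4980), a), 50)  # symmetric
  expect_error(cnv_distance(a, rec(1000, 5000, chrom = "2")),
               "same chromosome")
})

test_that("binary similarity thresholds at the genomic window, boundary excluded", {
  a <- rec(1000, 5000)
  expect_equal(cnv_similarity(a, rec(1050, 5000)), 1L)   # distance 50
  expect_equal(cnv_similarity(a, rec(1200, 5000)), 0L)   # distance 200
  expect_equal(cnv_similarity(a, rec(1100, 5000)), 0L)   # distance == gw
  expect_error(cnv_similarity(a, a, gw = -1), "gw")
})

test_that("graph edges require same chromosome, same type and distance < gw", {
  # identical coordinates, opposite type: no edge
  x <- cnv_records("1", c(1000, 1000), c(5000, 5000), c("gain", "loss"),
                   id = c("a", "b"))
  g <- build_similarity_graph(x, 100)
  expect_equal(nrow(g$edges), 0L)

  # far-apart CNVs: isolated nodes
  x <- rec(c(1e4, 5e4, 9e4), c(2e4, 6e4, 9.5e4), id = c("a", "b", "c"))
  expect_equal(nrow(build_similarity_graph(x, 100)$edges), 0L)

  # three mutually close CNVs form a triangle (oracle: all-pairs distances)
  x <- rec(c(1000, 1030, 1060), c(5000, 5010, 5050), id = c("a", "b", "c"))
  d <- outer(seq_len(3), seq_len(3), function(i, j)
    pmax(abs(x$start[i] - x$start[j]), abs(x$end[i] - x$end[j])))
  expect_true(all(d[upper.tri(d)] < 100))
  expect_equal(nrow(build_similarity_graph(x, 100)$edges), 3L)
})

test_that("windowed graph construction equals the naive all-pairs graph", {
  set.seed(7)
  for (trial in 1:10) {
    n <- 40
    starts <- sort(sample(5e4, n))
    x <- cnv_records("1", starts, starts + sample(200:2000, n, replace = TRUE),
                     sample(c("gain", "loss"), n, replace = TRUE),
                     id = sprintf("n%02d", 1:n))
    g <- build_similarity_graph(x, 100)
    have <- sort(paste(pmin(g$edges$a, g$edges$b), pmax(g$edges$a, g$edges$b)))
    want <- character(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (x$cnv_type[i] == x$cnv_type[j] &&
          max(abs(x$start[i] - x$start[j]), abs(x$end[i] - x$end[j])) < 100)
        want <- c(want, paste(min(x$id[i], x$id[j]), max(x$id[i], x$id[j])))
    }
    expect_identical(have, sort(want))
  }
})

test_that("clique partition handles the canonical small graphs", {
  # fully connected component collapses to one clique
  x <- rec(c(1000, 1010, 1020, 1030), c(5000, 5010, 5020, 5030),
           id = c("a", "b", "c", "d"))
  p <- partition_into_cliques(build_similarity_graph(x, 100))
  expect_equal(p, list(c("a", "b", "c", "d")))

  # path A-B-C: sizes {2,1}; deterministic tie-break picks {A,B}
  g <- structure(list(nodes = c("A", "B", "C"),
                      edges = data.table::data.table(a = c("A", "B"),
                                                     b = c("B", "C"))),
                 class = "cnv_simgraph")
  p <- partition_into_cliques(g)
  expect_equal(p, list(c("A", "B"), "C"))

  # empty graph
  expect_equal(partition_into_cliques(
    build_similarity_graph(rec(numeric(0), numeric(0)), 100)), list())
})

test_that("clique partition matches exhaustive enumeration on random graphs", {
  set.seed(11)
  for (trial in 1:40) {
    inst <- random_graph_instance(n = sample(2:10, 1), p = runif(1, 0.2, 0.8))
    got <- partition_into_cliques(inst$graph)
    got_sizes <- sort(lengths(got), decreasing = TRUE)
    expect_equal(got_sizes, oracle_clique_sizes(inst$adj, inst$ids))
    # partition property
    expect_setequal(unlist(got), inst$ids)
    expect_equal(length(unlist(got)), length(inst$ids))
  }
})

test_that("unify produces median representatives and partitions the input", {
  # identity on a single CNV
  x <- rec(1000, 5000, id = "solo")
  u <- unify(x)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 1000); expect_equal(u$end, 5000)
  expect_equal(u$n_members, 1L)

  # per-coordinate median of members (round half up)
  x <- rec(c(1000, 1040, 1080), c(5000, 5000, 5060), id = c("a", "b", "c"))
  u <- unify(x, 100)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 1040)
  expect_equal(u$end, 5000)

  # even member count: median halfway, rounded up
  x <- rec(c(1000, 1041), c(5000, 5001), id = c("a", "b"))
  u <- unify(x, 100)
  expect_equal(u$start, 1021)  # median 1020.5 -> 1021
})

test_that("unify counts distinct carrier samples per group", {
  x <- cnv_records("1", c(1000, 1010, 1020), c(5000, 5010, 5020), "loss",
                   sample_id = c("s1", "s1", "s2"), group = "EAS",
                   id = c("a", "b", "c"))
  u <- unify(x, 100)
  expect_equal(u$n_members, 3L)
  expect_equal(u$carriers_EAS, 2L)
  expect_equal(u$n_samples, 2L)
})

test_that("unification satisfies partition and within-clique distance invariants", {
  set.seed(3)
  n <- 60
  starts <- cumsum(sample(200:1500, n, replace = TRUE))
  x <- cnv_records("1", starts + sample(-30:30, n, replace = TRUE),
                   starts + 5000 + sample(-30:30, n, replace = TRUE),
                   "loss", id = sprintf("c%02d", 1:n))
  u <- unify(x, 100)
  members <- strsplit(u$member_ids, ",")
  expect_setequal(unlist(members), x$id)
  expect_equal(sum(u$n_members), n)
  for (m in members) {
    if (length(m) > 1) {
      sub <- x[match(m, x$id), ]
      for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
        expect_lt(max(abs(sub$start[i] - sub$start[j]),
                      abs(sub$end[i] - sub$end[j])), 100)
      }
    }
  }
})

test_that("jittered replicates of one CNV unify back to a single CNV", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- jittered_replicates(k = sample(2:8, 1), gw = 100)
    u <- unify(x, 100)
    expect_equal(nrow(u), 1L)
    expect_equal(u$n_members, nrow(x))
  }
})

test_that("unify is deterministic for identical input", {
  set.seed(5)
  x <- jittered_replicates(6)
  expect_identical(as.data.frame(unify(x, 100)), as.data.frame(unify(x, 100)))
})

test_that("group allele frequency divides carriers by group size", {
  x <- cnv_records("1", c(1000, 1010), c(5000, 5010), "loss",
                   sample_id = c("s1", "s2"), group = "EAS", id = c("a", "b"))
  u <- unify(x, 100, group_sizes = c(EAS = 100, FIN = 10))
  expect_equal(u$af_EAS, 0.02)
  expect_equal(u$af_FIN, 0)
  expect_equal(u$af_overall, 2 / 110)
  expect_error(unify(x, 100, group_sizes = c(FIN = 10)), "EAS")
})
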
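# Independent brute-force oracles used by unit and acceptance tests. These
# deliberately share no code with the package implementation.

# Iterative maximum-clique removal by exhaustive subset enumeration (n <= ~12).
# Ties among equal-size cliques break toward the lexicographically smallest
# sorted member-id tuple. Returns clique sizes, largest first.
oracle_clique_sizes <- function(adj, ids) {
  diag(adj) <- TRUE
  sizes <- integer(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    if (length(remaining) == 1) {
      sizes <- c(sizes, 1L)
      remaining <- integer(0)
      break
    }
    best <- NULL
    for (k in seq(length(remaining), 1)) {
      combs <- utils::combn(remaining, k)
      found <- list()
      for (j in seq_len(ncol(combs))) {
        v <- combs[, j]
        if (all(adj[v, v])) found[[length(found) + 1]] <- v
      }
      if (length(found)) {
        keys <- vapply(found, function(v)
          paste(sort(ids[v]), collapse = "\x01"), character(1))
        best <- found[[which(keys == min(keys))[1]]]
        break
      }
    }
    sizes <- c(sizes, length(best))
    remaining <- setdiff(remaining, best)
  }
  sort(sizes, decreasing = TRUE)
}

# random similarity-graph instance (adjacency + the package's graph object)
random_graph_instance <- function(n, p, prefix = "N") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    up <- which(upper.tri(adj))
    adj[up] <- stats::runif(length(up)) < p
    adj <- adj | t(adj)
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- structure(list(nodes = ids,
                      edges = data.table::data.table(a = ids[idx[, 1]],
                                                     b = ids[idx[, 2]])),
                 class = "cnv_simgraph")
  list(adj = adj, ids = ids, graph = g)
}

# O(n^2) pairwise Mann-Whitney AUC
oracle_auc <- function(scores, labels) {
  p <- scores[labels == 1]; n <- scores[labels == 0]
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# k jittered replicates of one true CNV (uniform jitter in (-gw/2, gw/2))
jittered_replicates <- function(k, gw = 100, start = 100000,
                                end = start + 50000,
                                chrom = "1", type = "loss") {
  js <- round(stats::runif(k, -gw / 2 + 1, gw / 2 - 1))
  je <- round(stats::runif(k, -gw / 2 + 1, gw / 2 - 1))
  cnv_records(chrom, start + js, end + je, type,
              id = sprintf("rep%02d", seq_len(k)))
}

# minimal annotation bundle over a handful of CNVs: every required source
# present, built from explicit per-CNV values so expectations are hand
# computable. `track_vals` is a named list feature -> data.frame(chrom, pos,
# score); unlisted tracks get a default distant position.
toy_bundle <- function(track_vals = list(), gene_tbl = NULL, regions = list(),
                       cdts = NULL, cdts_thresholds = c(pct1 = -2, pct5 = -1)) {
  far <- data.frame(chrom = "99", pos = 1, score = 0)
  tracks <- list()
  for (nm in c("FATHMM", "LR", "LRT", "MutationAssessor", "MutationTaster",
               "PolyPhen2", "RadialSVM", "SIFT", "VEST3",
               "CADD", "GERP", "phyloP100way", "phyloP46way", "SiPhy29way"))
    tracks[[nm]] <- if (nm %in% names(track_vals)) track_vals[[nm]] else far
  tracks$CDTS <- if (!is.null(cdts)) cdts else far
  if (is.null(gene_tbl))
    gene_tbl <- data.frame(chrom = "99", start = 1, end = 2, gene = "g0",
                           score = 0.5)
  genes <- list(pLI = gene_tbl, Episcore = gene_tbl, GHIS = gene_tbl,
                coding_genes = gene_tbl)
  fr <- data.frame(chrom = "99", start = 1, end = 2)
  regs <- list()
  for (nm in c("PLS", "pELS", "dELS", "CTCF_bound", "CTCF_only",
               "DNase_H3K4me3"))
    regs[[nm]] <- if (nm %in% names(regions)) regions[[nm]] else fr
  xcnv_bundle(tracks, genes, regs, cdts_thresholds)
}
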
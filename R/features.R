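# Feature engine: 30 named columns in four groups.
#   universal   (4): CNV length, CNV type, gain-PAF, loss-PAF
#   coding     (13): 9 SNV deleteriousness aggregates + 3 haploinsufficiency
#                    gene scores + count of overlapped protein-coding genes
#   noncoding   (8): CDTS 1%/5% constrained-base fractions + 6 cCRE classes
#   genome-wide (5): CADD, GERP, phyloP 100-way/46-way, SiPhy 29-way
# Positional tracks are aggregated as the mean over scored (covered) bases;
# cells with no covering annotation are missing and later imputed with the
# per-column training minimum.

#' The 30-feature schema
#'
#' Named feature columns by group. The coding group holds nine SNV-level
#' deleteriousness aggregates, three haploinsufficiency gene scores
#' (pLI / Episcore / GHIS) and one configurable slot defaulting to the count
#' of overlapped protein-coding genes; the schema is data, so an alternative
#' coding column set can be swapped in.
#'
#' @param coding_extra name of the 13th coding column (default
#'   `"n_coding_genes"`).
#' @return Named list with elements `universal`, `coding`, `noncoding`,
#'   `genomewide` and `all` (the 30 names in matrix order).
#' @export
xcnv_feature_schema <- function(coding_extra = "n_coding_genes") {
  s <- list(
    universal = c("cnv_length", "cnv_type_gain", "paf_gain", "paf_loss"),
    coding = c("FATHMM", "LR", "LRT", "MutationAssessor", "MutationTaster",
               "PolyPhen2", "RadialSVM", "SIFT", "VEST3",
               "pLI", "Episcore", "GHIS", coding_extra),
    noncoding = c("CDTS_pct1", "CDTS_pct5",
                  "PLS", "pELS", "dELS", "CTCF_bound", "CTCF_only",
                  "DNase_H3K4me3"),
    genomewide = c("CADD", "GERP", "phyloP100way", "phyloP46way", "SiPhy29way")
  )
  s$all <- unlist(s, use.names = FALSE)
  stopifnot(length(s$all) == 30)
  s
}

# track names expected in a bundle, by role
.snv_tracks <- function() c("FATHMM", "LR", "LRT", "MutationAssessor",
                            "MutationTaster", "PolyPhen2", "RadialSVM",
                            "SIFT", "VEST3")
.gw_tracks <- function() c("CADD", "GERP", "phyloP100way", "phyloP46way",
                           "SiPhy29way")
.gene_tables <- function() c("pLI", "Episcore", "GHIS")
.ccre_sets <- function() c("PLS", "pELS", "dELS", "CTCF_bound", "CTCF_only",
                           "DNase_H3K4me3")

#' Assemble an annotation bundle
#'
#' Container for every annotation source the feature engine consumes.
#'
#' @param tracks named list of per-position score tracks, each a data.frame
#'   `chrom, pos, score` (sparse: not every base is scored). Must include the
#'   nine SNV deleteriousness tracks, the five genome-wide tracks, and `CDTS`.
#' @param genes named list of gene tables `chrom, start, end, gene, score`;
#'   must include `pLI`, `Episcore`, `GHIS` and `coding_genes` (score column
#'   ignored for the count feature).
#' @param regions named list of BED-like region tables `chrom, start, end` for
#'   the six cCRE classes.
#' @param cdts_thresholds numeric `c(pct1 = ..., pct5 = ...)`: the genome-wide
#'   1% and 5% CDTS percentile values (inputs, not recomputed here).
#' @return A list of class `xcnv_bundle`.
#' @export
xcnv_bundle <- function(tracks, genes, regions, cdts_thresholds) {
  need_tracks <- c(.snv_tracks(), .gw_tracks(), "CDTS")
  miss <- setdiff(need_tracks, names(tracks))
  if (length(miss)) stop("bundle missing positional track(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(c(.gene_tables(), "coding_genes"), names(genes))
  if (length(miss)) stop("bundle missing gene table(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(.ccre_sets(), names(regions))
  if (length(miss)) stop("bundle missing cCRE region set(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(c("pct1", "pct5") %in% names(cdts_thresholds)))
  tracks <- lapply(tracks, function(tr) {
    tr <- as.data.table(tr)[, .(chrom = normalize_chrom(chrom), pos, score)]
    if (any(!is.finite(tr$score))) stop("track scores must be finite")
    tr
  })
  genes <- lapply(genes, function(g) {
    g <- as.data.table(g)
    g[, chrom := normalize_chrom(chrom)]
    g
  })
  regions <- lapply(regions, function(r) {
    r <- as.data.table(r)[, .(chrom = normalize_chrom(chrom), start, end)]
    r
  })
  structure(list(tracks = tracks, genes = genes, regions = regions,
                 cdts_thresholds = cdts_thresholds),
            class = "xcnv_bundle")
}

# overlap-join positions of a track onto CNV intervals; returns data.table
# (id, score) with one row per covered position
.positions_in <- function(cnvs, track) {
  tr <- as.data.table(track)
  tr <- data.table(chrom = normalize_chrom(tr$chrom), start = tr$pos,
                   end = tr$pos, score = tr$score)
  q <- data.table(id = cnvs$id, chrom = normalize_chrom(cnvs$chrom),
                  start = cnvs$start, end = cnvs$end)
  setkey(tr, chrom, start, end)
  foverlaps(q, tr, type = "any", nomatch = NULL)[, .(id, score)]
}

#' Aggregate a per-position score track over CNVs
#'
#' Mean of the track's scores at positions inside each CNV. The denominator
#' is the covered length — the number of scored positions inside the CNV —
#' so sparse annotation coverage is not conflated with low deleteriousness;
#' `denominator = "total"` divides the score sum by the full CNV length
#' instead. CNVs overlapping no scored position are missing (`NA`).
#'
#' @param cnvs a `cnv_records` table.
#' @param track data.frame `chrom, pos, score`.
#' @param denominator `"covered"` (default) or `"total"`.
#' @return Numeric vector aligned with `cnvs` rows; `NA` where uncovered.
#' @export
aggregate_positional <- function(cnvs, track, denominator = c("covered", "total")) {
  denominator <- match.arg(denominator)
  hits <- .positions_in(cnvs, track)
  agg <- hits[, .(s = sum(score), n = .N), by = id]
  out <- rep(NA_real_, nrow(cnvs))
  i <- match(agg$id, cnvs$id)
  out[i] <- if (denominator == "covered") agg$s / agg$n else
    agg$s / cnv_length(cnvs)[i]
  out
}

#' Gene-level score of CNVs
#'
#' Reduces the scores of genes overlapping each CNV. Default `max`: the worst
#' (most haploinsufficiency-intolerant) gene dominates the CNV's score.
#'
#' @param cnvs a `cnv_records` table.
#' @param table gene table `chrom, start, end, gene, score`.
#' @param mode `"max"` (default) or `"mean"`.
#' @return Numeric vector; `NA` where no gene overlaps.
#' @export
gene_score <- function(cnvs, table, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  g <- as.data.table(table)[, .(chrom = normalize_chrom(chrom), start, end, score)]
  q <- data.table(id = cnvs$id, chrom = normalize_chrom(cnvs$chrom),
                  start = cnvs$start, end = cnvs$end)
  setkey(g, chrom, start, end)
  hits <- foverlaps(q, g, type = "any", nomatch = NULL)
  if (nrow(hits) == 0) return(rep(NA_real_, nrow(cnvs)))
  agg <- hits[, .(v = if (mode == "max") max(score) else mean(score)), by = id]
  out <- rep(NA_real_, nrow(cnvs))
  out[match(agg$id, cnvs$id)] <- agg$v
  out
}

# number of genes in a table overlapping each CNV (0 when none)
gene_count <- function(cnvs, table) {
  g <- as.data.table(table)[, .(chrom = normalize_chrom(chrom), start, end)]
  q <- data.table(id = cnvs$id, chrom = normalize_chrom(cnvs$chrom),
                  start = cnvs$start, end = cnvs$end)
  setkey(g, chrom, start, end)
  hits <- foverlaps(q, g, type = "any", nomatch = NULL)
  agg <- hits[, .N, by = id]
  out <- rep(0, nrow(cnvs))
  out[match(agg$id, cnvs$id)] <- agg$N
  out
}

# merge overlapping intervals so union coverage can be summed
.reduce_intervals <- function(r) {
  r <- as.data.table(r)[order(chrom, start, end)]
  r[, grp := {
    cm <- cummax(end)
    cumsum(c(TRUE, start[-1] > head(cm, -1)))
  }, by = chrom]
  r[, .(start = min(start), end = max(end)), by = .(chrom, grp)][, .(chrom, start, end)]
}

#' Regulatory-region score of CNVs
#'
#' Default `overlap_fraction`: base pairs of the CNV covered by the region
#' set (intervals merged first) divided by CNV length, a fraction in
#' `[0, 1]`. The alternative `length_ratio` mode divides CNV length by the
#' total length of the regulatory intervals overlapping it (0 when none) —
#' an unbounded ratio retained for comparability with the literal published
#' formula.
#'
#' @param cnvs a `cnv_records` table.
#' @param rs region table `chrom, start, end`.
#' @param mode `"overlap_fraction"` (default) or `"length_ratio"`.
#' @return Nonnegative numeric vector (in `[0, 1]` for the default mode).
#' @export
region_fraction <- function(cnvs, rs, mode = c("overlap_fraction", "length_ratio")) {
  mode <- match.arg(mode)
  out <- rep(0, nrow(cnvs))
  rs <- as.data.table(rs)
  if (nrow(rs) == 0) return(out)
  r <- .reduce_intervals(rs[, .(chrom = normalize_chrom(chrom), start, end)])
  q <- data.table(id = cnvs$id, chrom = normalize_chrom(cnvs$chrom),
                  start = cnvs$start, end = cnvs$end)
  setkey(r, chrom, start, end)
  hits <- foverlaps(q, r, type = "any", nomatch = NULL)
  if (nrow(hits) == 0) return(out)
  if (mode == "overlap_fraction") {
    agg <- hits[, .(bp = sum(pmin(end, i.end) - pmax(start, i.start) + 1)), by = id]
    i <- match(agg$id, cnvs$id)
    out[i] <- agg$bp / cnv_length(cnvs)[i]
  } else {
    agg <- hits[, .(rl = sum(end - start + 1)), by = id]
    i <- match(agg$id, cnvs$id)
    out[i] <- cnv_length(cnvs)[i] / agg$rl
  }
  out
}

#' Constrained-base fraction from a CDTS track
#'
#' Fraction of each CNV's scored positions whose context-dependent tolerance
#' score lies below the genome-wide 1% (or 5%) percentile threshold — i.e.
#' the share of annotated bases in the most variation-depleted tail.
#' Thresholds are supplied, not recomputed from the query batch.
#'
#' @param cnvs a `cnv_records` table.
#' @param cdts track `chrom, pos, score`.
#' @param percentile 1 or 5.
#' @param thresholds numeric `c(pct1 = ..., pct5 = ...)`.
#' @return Numeric vector of fractions; `NA` where no scored position overlaps.
#' @export
cdts_feature <- function(cnvs, cdts, percentile = c(1, 5), thresholds) {
  percentile <- as.character(percentile[1])
  if (!percentile %in% c("1", "5")) stop("percentile must be 1 or 5")
  thr <- thresholds[[paste0("pct", percentile)]]
  if (is.null(thr) || !is.finite(thr)) stop("thresholds must supply pct", percentile)
  hits <- .positions_in(cnvs, cdts)
  agg <- hits[, .(f = mean(score < thr)), by = id]
  out <- rep(NA_real_, nrow(cnvs))
  out[match(agg$id, cnvs$id)] <- agg$f
  out
}

#' Universal features
#'
#' CNV length (bp), type encoding (gain = 1, loss = 0), and the population
#' allele frequency split into a gain-PAF and a loss-PAF column: the AF from
#' [lookup_af()] lands in the column matching the CNV's own type, 0 in the
#' other.
#'
#' @param cnvs a `cnv_records` table.
#' @param afdb an `af_database` (NULL for all-zero PAF columns).
#' @param ro_min reciprocal-overlap threshold for AF lookup.
#' @return data.table with columns `cnv_length`, `cnv_type_gain`, `paf_gain`,
#'   `paf_loss`.
#' @export
universal_features <- function(cnvs, afdb = NULL, ro_min = 0.7) {
  af <- if (is.null(afdb)) numeric(nrow(cnvs)) else lookup_af(cnvs, afdb, ro_min)
  is_gain <- cnvs$cnv_type == "gain"
  data.table(cnv_length = cnv_length(cnvs),
             cnv_type_gain = as.numeric(is_gain),
             paf_gain = ifelse(is_gain, af, 0),
             paf_loss = ifelse(is_gain, 0, af))
}

#' Build the 30-column feature matrix
#'
#' Assembles all four feature groups in fixed schema order, preserving row
#' order. Cells with no covering annotation are `NA` and flagged in the
#' missingness mask; call [impute_missing()] before model fitting.
#'
#' @param cnvs a `cnv_records` table.
#' @param bundle an `xcnv_bundle`.
#' @param afdb an `af_database` (or NULL).
#' @param ro_min reciprocal-overlap threshold for AF lookup.
#' @param gene_mode reduction for gene scores (`"max"` or `"mean"`).
#' @param region_mode cCRE scoring mode (see [region_fraction()]).
#' @param denominator positional aggregation denominator (see
#'   [aggregate_positional()]).
#' @return Numeric matrix of class `xcnv_features`, rownames = CNV ids, with
#'   attributes `missing` (logical mask) and `schema`.
#' @export
build_feature_matrix <- function(cnvs, bundle, afdb = NULL, ro_min = 0.7,
                                 gene_mode = "max",
                                 region_mode = "overlap_fraction",
                                 denominator = "covered") {
  if (!inherits(bundle, "xcnv_bundle")) stop("bundle must be an xcnv_bundle")
  schema <- xcnv_feature_schema()
  m <- matrix(NA_real_, nrow = nrow(cnvs), ncol = 30,
              dimnames = list(cnvs$id, schema$all))
  uf <- universal_features(cnvs, afdb, ro_min)
  for (cc in schema$universal) m[, cc] <- uf[[cc]]
  for (tr in .snv_tracks())
    m[, tr] <- aggregate_positional(cnvs, bundle$tracks[[tr]], denominator)
  for (gt in .gene_tables())
    m[, gt] <- gene_score(cnvs, bundle$genes[[gt]], gene_mode)
  m[, "n_coding_genes"] <- gene_count(cnvs, bundle$genes$coding_genes)
  m[, "CDTS_pct1"] <- cdts_feature(cnvs, bundle$tracks$CDTS, 1, bundle$cdts_thresholds)
  m[, "CDTS_pct5"] <- cdts_feature(cnvs, bundle$tracks$CDTS, 5, bundle$cdts_thresholds)
  for (rs in .ccre_sets())
    m[, rs] <- region_fraction(cnvs, bundle$regions[[rs]], region_mode)
  for (tr in .gw_tracks())
    m[, tr] <- aggregate_positional(cnvs, bundle$tracks[[tr]], denominator)
  structure(m, missing = is.na(m), schema = schema,
            class = c("xcnv_features", "matrix", "array"))
}

#' Per-column minima of observed cells
#'
#' @param m an `xcnv_features` matrix (may contain `NA`).
#' @return Named numeric vector of column minima over non-missing cells.
#' @export
feature_minima <- function(m) {
  apply(m, 2, function(v) suppressWarnings(min(v, na.rm = TRUE)))
}

#' Minimum-value imputation
#'
#' Replaces every missing cell with the column minimum over the non-missing
#' cells of the reference (training) matrix — at training time the matrix
#' itself; at prediction time the stored training matrix or its minima — so
#' uncovered CNVs take the least-deleterious observed value.
#'
#' @param m an `xcnv_features` matrix.
#' @param reference a training `xcnv_features` matrix, a named vector of
#'   training column minima, or NULL to use `m` itself.
#' @return `m` with no missing cells; the `missing` attribute still marks
#'   which cells were imputed.
#' @export
impute_missing <- function(m, reference = NULL) {
  mins <- if (is.null(reference)) feature_minima(m)
          else if (is.matrix(reference)) feature_minima(reference)
          else reference
  mins <- mins[colnames(m)]
  bad <- colnames(m)[apply(m, 2, function(v) all(is.na(v)))]
  bad <- bad[!is.finite(mins[bad])]
  if (length(bad))
    stop("feature column(s) entirely missing in training data: ",
         paste(bad, collapse = ", "))
  mask <- is.na(m)
  for (j in seq_len(ncol(m))) {
    if (any(mask[, j])) {
      if (!is.finite(mins[j]))
        stop("feature column(s) entirely missing in training data: ",
             colnames(m)[j])
      m[mask[, j], j] <- mins[j]
    }
  }
  structure(m, missing = mask, schema = attr(m, "schema"),
            class = c("xcnv_features", "matrix", "array"))
}
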
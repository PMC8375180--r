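# Evaluation suite: confusion-matrix metrics (MCC, accuracy, F1,
# Fowlkes-Mallows, sensitivity, specificity), rank-based ROC AUC,
# train/validation leakage filtering at 50% reciprocal overlap, and
# performance stratified by CNV length bin and type.

#' Confusion-matrix performance metrics
#'
#' Vectorized over parallel count vectors. MCC is
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, reported as 0 with
#' `mcc_zero_denom = TRUE` when the denominator vanishes (the statistic is
#' undefined there); accuracy `(TP+TN)/total`; F1 `2TP/(2TP+FP+FN)`;
#' Fowlkes-Mallows `sqrt(precision * recall)`; sensitivity `TP/(TP+FN)`;
#' specificity `TN/(TN+FP)`.
#'
#' @param tp,tn,fp,fn nonnegative counts (recycled).
#' @return data.table with columns `mcc, accuracy, f1, fowlkes_mallows,
#'   sensitivity, specificity, mcc_zero_denom`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  n <- max(length(tp), length(tn), length(fp), length(fn))
  tp <- rep_len(as.numeric(tp), n); tn <- rep_len(as.numeric(tn), n)
  fp <- rep_len(as.numeric(fp), n); fn <- rep_len(as.numeric(fn), n)
  if (any(tp < 0 | tn < 0 | fp < 0 | fn < 0)) stop("counts must be nonnegative")
  if (any(tp + tn + fp + fn == 0)) stop("all-zero confusion counts")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  zero <- denom == 0
  mcc <- ifelse(zero, 0, (tp * tn - fp * fn) / ifelse(zero, 1, denom))
  data.table(
    mcc = mcc,
    accuracy = (tp + tn) / (tp + tn + fn + fp),
    f1 = ifelse(2 * tp + fp + fn == 0, NA_real_, 2 * tp / (2 * tp + fp + fn)),
    fowlkes_mallows = ifelse(tp + fp == 0 | tp + fn == 0, NA_real_,
                             sqrt(tp / (tp + fp) * tp / (tp + fn))),
    sensitivity = ifelse(tp + fn == 0, NA_real_, tp / (tp + fn)),
    specificity = ifelse(tn + fp == 0, NA_real_, tn / (tn + fp)),
    mcc_zero_denom = zero
  )
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic: the probability a random positive outscores a
#' random negative, ties counted 1/2. Threshold-free and invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (1/TRUE = positive); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Remove training CNVs that leak validation information
#'
#' Drops every training CNV with reciprocal overlap `>= ro_min` (default 50%)
#' to any validation CNV, regardless of CNV type (the conservative choice:
#' more is dropped). The number dropped is reported via message and attribute.
#'
#' @param train,validation `cnv_records` tables.
#' @param ro_min reciprocal-overlap threshold (default 0.5).
#' @return The retained training records, with attribute `n_dropped`.
#' @export
leakage_filter <- function(train, validation, ro_min = 0.5) {
  if (nrow(train) == 0 || nrow(validation) == 0) {
    message("leakage filter: 0 of ", nrow(train), " training CNVs dropped")
    return(structure(train, n_dropped = 0L))
  }
  v <- data.table(chrom = normalize_chrom(validation$chrom),
                  start = validation$start, end = validation$end)
  q <- data.table(qi = seq_len(nrow(train)),
                  chrom = normalize_chrom(train$chrom),
                  start = train$start, end = train$end)
  setkey(v, chrom, start, end)
  hits <- foverlaps(q, v, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  drop <- integer(0)
  if (nrow(hits)) {
    hits[, ro := {
      ov <- pmin(end, i.end) - pmax(start, i.start) + 1
      pmin(ov / (end - start + 1), ov / (i.end - i.start + 1))
    }]
    drop <- unique(hits[ro >= ro_min, qi])
  }
  message("leakage filter: ", length(drop), " of ", nrow(train),
          " training CNVs dropped (RO >= ", ro_min, ")")
  out <- train[!seq_len(nrow(train)) %in% drop, ]
  setattr(out, "n_dropped", length(drop))
  out
}

#' Collapse five-tier labels to binary
#'
#' Pathogenic and likely pathogenic become positives (1), benign and likely
#' benign negatives (0); variants of uncertain significance are `NA` and are
#' excluded from binary metrics.
#'
#' @param labels5 character vector of five-tier labels.
#' @return Integer vector of 1/0/NA.
#' @export
collapse_labels <- function(labels5) {
  ifelse(labels5 %in% c("pathogenic", "likely_pathogenic"), 1L,
         ifelse(labels5 %in% c("benign", "likely_benign"), 0L, NA_integer_))
}

#' Stratified performance report
#'
#' One metrics row per stratum: all CNVs, four length bins (0-10 kb,
#' 10-100 kb, 100 kb-1 Mb, 1-10 Mb; bins are left-open right-closed so a
#' 10,001 bp CNV falls in the second bin), and gain/loss. Empty strata are
#' flagged and carry no metrics.
#'
#' @param cnvs a `cnv_records` table.
#' @param predicted binary predictions (1 = called pathogenic), aligned with
#'   `cnvs`; `NA` rows are dropped.
#' @param truth binary truth labels, aligned; `NA` rows are dropped.
#' @return data.table: `stratum, n, tp, tn, fp, fn`, the
#'   [confusion_metrics()] columns, and `empty`.
#' @export
stratified_report <- function(cnvs, predicted, truth) {
  if (length(predicted) != nrow(cnvs) || length(truth) != nrow(cnvs))
    stop("predictions and truth must align with cnvs rows")
  keep <- !is.na(predicted) & !is.na(truth)
  cnvs <- cnvs[keep, ]; predicted <- predicted[keep]; truth <- truth[keep]
  len <- cnv_length(cnvs)
  bins <- cut(len, breaks = c(0, 1e4, 1e5, 1e6, 1e7), right = TRUE,
              labels = c("0-10kb", "10kb-100kb", "100kb-1Mb", "1Mb-10Mb"))
  strata <- c(list(all = rep(TRUE, nrow(cnvs))),
              setNames(lapply(levels(bins), function(b) bins == b), levels(bins)),
              list(gain = cnvs$cnv_type == "gain",
                   loss = cnvs$cnv_type == "loss"))
  rows <- lapply(names(strata), function(s) {
    i <- strata[[s]]
    if (!any(i)) return(data.table(stratum = s, n = 0L, empty = TRUE))
    counts <- data.table(stratum = s, n = sum(i),
                         tp = sum(predicted[i] == 1 & truth[i] == 1),
                         tn = sum(predicted[i] == 0 & truth[i] == 0),
                         fp = sum(predicted[i] == 1 & truth[i] == 0),
                         fn = sum(predicted[i] == 0 & truth[i] == 1),
                         empty = FALSE)
    cbind(counts, confusion_metrics(counts$tp, counts$tn, counts$fp, counts$fn))
  })
  rbindlist(rows, fill = TRUE)
}

#' Relative improvement of one metric over another
#'
#' `(a - b) / |b| * 100`, in percent. An MCC of 0.65 against a baseline of
#' 0.27 is a 140.7% improvement; against -0.08, 912.5%.
#'
#' @param a new metric value.
#' @param b baseline metric value (nonzero).
#' @return Percent improvement.
#' @export
relative_improvement <- function(a, b) {
  if (any(b == 0)) stop("baseline metric is 0; relative improvement undefined")
  (a - b) / abs(b) * 100
}
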
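# Population allele-frequency database: unified CNVs from a natural
# population, queried at 70% reciprocal overlap. A query that matches no
# database entry is assigned AF 0 (assumed rare).

#' Construct an allele-frequency database
#'
#' @param entries data.frame with columns `chrom`, `start`, `end`, `cnv_type`,
#'   `af_overall` and optionally `af_<GROUP>` columns; AFs must lie in
#'   `[0, 1]`.
#' @param group_sizes optional named vector of per-group sample counts
#'   (positive), stored as an attribute for provenance.
#' @return A `data.table` of class `af_database`.
#' @seealso [unified_to_afdb()] to build one from [unify()] output.
#' @export
af_database <- function(entries, group_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "cnv_type", "af_overall") %in%
                  names(entries)))
  db <- as.data.table(entries)
  db[, chrom := normalize_chrom(chrom)]
  afcols <- grep("^af_", names(db), value = TRUE)
  for (cc in afcols) {
    v <- db[[cc]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1))
      stop("allele frequencies in column ", cc, " must lie in [0, 1]")
  }
  if (!is.null(group_sizes) && any(group_sizes <= 0))
    stop("group_sizes must be positive")
  setattr(db, "group_sizes", group_sizes)
  setattr(db, "class", c("af_database", class(data.table())))
  db[]
}

#' Build an AF database from unified CNVs
#'
#' @param u a `unified_cnvs` table carrying `af_*` columns (i.e. produced with
#'   `group_sizes`).
#' @param group_sizes the named per-group sample counts used.
#' @return An `af_database`.
#' @export
unified_to_afdb <- function(u, group_sizes) {
  if (!"af_overall" %in% names(u))
    u <- group_allele_frequency(u, group_sizes)
  keep <- c("chrom", "start", "end", "cnv_type", "af_overall",
            grep("^af_[A-Z]", names(u), value = TRUE))
  af_database(as.data.table(u)[, keep, with = FALSE], group_sizes)
}

#' Look up population allele frequency for query CNVs
#'
#' For each query, database entries of the same chromosome and CNV type with
#' reciprocal overlap `>= ro_min` are candidates; the AF of the best-RO match
#' is returned (ties broken toward the higher AF, for determinism). Queries
#' with no qualifying entry get 0.
#'
#' @param q a `cnv_records` table of queries.
#' @param db an `af_database`.
#' @param ro_min reciprocal-overlap threshold in `(0, 1]` (default 0.7).
#' @return Numeric vector of `af_overall` values, one per query row.
#' @export
lookup_af <- function(q, db, ro_min = 0.7) {
  if (length(ro_min) != 1 || is.na(ro_min) || ro_min <= 0 || ro_min > 1)
    stop("ro_min must lie in (0, 1]")
  out <- numeric(nrow(q))
  if (nrow(q) == 0 || nrow(db) == 0) return(out)
  qt <- data.table(qi = seq_len(nrow(q)), chrom = normalize_chrom(q$chrom),
                   cnv_type = q$cnv_type, start = q$start, end = q$end)
  dbt <- data.table(di = seq_len(nrow(db)), chrom = db$chrom,
                    cnv_type = db$cnv_type, start = db$start, end = db$end,
                    af = db$af_overall)
  setkey(dbt, chrom, cnv_type, start, end)
  hits <- foverlaps(qt, dbt, by.x = c("chrom", "cnv_type", "start", "end"),
                    type = "any", nomatch = NULL)
  if (nrow(hits)) {
    hits[, ro := {
      ov <- pmin(end, i.end) - pmax(start, i.start) + 1
      pmin(ov / (end - start + 1), ov / (i.end - i.start + 1))
    }]
    hits <- hits[ro >= ro_min]
    if (nrow(hits)) {
      best <- hits[order(qi, -ro, -af), .SD[1], by = qi]
      out[best$qi] <- best$af
    }
  }
  out
}
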
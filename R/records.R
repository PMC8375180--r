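#' @import data.table
#' @importFrom stats median quantile rnorm runif rbinom plogis qlogis setNames sd
#' @importFrom utils head tail
NULL

#' Ethnic group codes
#'
#' The nine population codes under which carrier counts and allele frequencies
#' are tabulated: African/African-American (AFR), Latino/Admixed American
#' (AMR), Ashkenazi Jewish (ASJ), East Asian (EAS), Finnish (FIN), Non-Finnish
#' European (NFE), South Asian (SAS), other (OTH) and unknown (UKN). Records
#' with no stated group are assigned \code{UKN} rather than rejected.
#'
#' @return Character vector of the nine group codes.
#' @export
xcnv_groups <- function() {
  c("AFR", "AMR", "ASJ", "EAS", "FIN", "NFE", "SAS", "OTH", "UKN")
}

#' Five-tier pathogenicity labels
#'
#' The ordered ACMG-style classes, from benign to pathogenic.
#'
#' @return Character vector of the five class labels in increasing severity.
#' @export
xcnv_classes <- function() {
  c("benign", "likely_benign", "uncertain", "likely_pathogenic", "pathogenic")
}

#' Normalize chromosome names
#'
#' Strips an optional \code{"chr"} prefix so calls from sources using either
#' convention compare equal. Case of the prefix is ignored; the remainder is
#' kept verbatim (so \code{"chrX"} and \code{"X"} both become \code{"X"}).
#'
#' @param chrom character vector of chromosome names.
#' @return Character vector without the \code{chr} prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Construct a validated CNV record table
#'
#' The package's core container: one row per CNV call, coordinates 1-based
#' inclusive. Invalid rows (start < 1, end < start, unknown type or group)
#' are a hard error, so every downstream operation can assume well-formed
#' intervals.
#'
#' @param chrom chromosome names (normalized via [normalize_chrom()]).
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`.
#' @param cnv_type `"gain"` or `"loss"`, recycled if length 1.
#' @param sample_id optional sample identifiers (NA allowed).
#' @param group optional ethnic group codes; NA is mapped to `"UKN"`.
#' @param label optional five-tier pathogenicity labels (NA allowed).
#' @param source optional free-text provenance tag.
#' @param id unique record identifiers; autogenerated (`cnv00001`, ...) when
#'   omitted.
#' @return A `data.table` of class `cnv_records` with columns
#'   `id, chrom, start, end, cnv_type, sample_id, group, label, source`.
#' @examples
#' cnv_records("chr1", 1000, 1999, "loss")
#' @export
cnv_records <- function(chrom, start, end, cnv_type,
                        sample_id = NA_character_, group = NA_character_,
                        label = NA_character_, source = NA_character_,
                        id = NULL) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("cnv%05d", seq_len(n))
  x <- data.table(
    id = as.character(id),
    chrom = normalize_chrom(rep_len(chrom, n)),
    start = as.numeric(start),
    end = as.numeric(end),
    cnv_type = rep_len(as.character(cnv_type), n),
    sample_id = rep_len(as.character(sample_id), n),
    group = rep_len(as.character(group), n),
    label = rep_len(as.character(label), n),
    source = rep_len(as.character(source), n)
  )
  x[is.na(group), group := "UKN"]
  validate_cnv_records(x)
  setattr(x, "class", c("cnv_records", class(data.table())))
  x[]
}

validate_cnv_records <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("id", "chrom", "start", "end", "cnv_type") %in% names(x)))
  if (anyDuplicated(x$id)) stop("duplicate CNV record ids")
  if (any(x$start < 1)) stop("start coordinates must be >= 1 (1-based inclusive)")
  if (any(x$end < x$start)) stop("end must be >= start")
  bad <- setdiff(unique(x$cnv_type), c("gain", "loss"))
  if (length(bad)) stop("cnv_type must be 'gain' or 'loss', got: ",
                        paste(bad, collapse = ", "))
  if ("group" %in% names(x)) {
    badg <- setdiff(unique(x$group[!is.na(x$group)]), xcnv_groups())
    if (length(badg)) stop("unknown ethnic group code(s): ",
                           paste(badg, collapse = ", "))
  }
  if ("label" %in% names(x)) {
    badl <- setdiff(unique(x$label[!is.na(x$label)]), xcnv_classes())
    if (length(badl)) stop("unknown pathogenicity label(s): ",
                           paste(badl, collapse = ", "))
  }
  invisible(x)
}

#' Length of a CNV in base pairs
#'
#' Inclusive-coordinate length, `end - start + 1`; a single-base interval has
#' length 1.
#'
#' @param x a `cnv_records` table (or any data.frame with `start`/`end`).
#' @return Numeric vector of lengths in bp.
#' @export
cnv_length <- function(x) {
  x$end - x$start + 1
}

#' Overlap between two interval sets in base pairs
#'
#' Element-wise overlap of paired intervals (both tables recycled to the
#' longer one). Intervals on different chromosomes, or disjoint intervals,
#' overlap by 0 bp; under the inclusive convention touching endpoints share
#' 1 bp.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`.
#' @return Numeric vector of overlap widths in bp, `>= 0`.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]) + 1
  ov[normalize_chrom(a$chrom[ia]) != normalize_chrom(b$chrom[ib])] <- 0
  pmax(0, ov)
}

#' Reciprocal overlap of two interval sets
#'
#' `min(overlap / length_a, overlap / length_b)`, the symmetric "X% in size
#' and location" match criterion used for allele-frequency lookup (70%) and
#' train/validation leakage filtering (50%). Equals 1 only for identical
#' intervals.
#'
#' @inheritParams overlap_bp
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  ov <- overlap_bp(a, b)
  pmin(ov / (a$end[ia] - a$start[ia] + 1), ov / (b$end[ib] - b$start[ib] + 1))
}

#' Build a bare interval table
#'
#' Convenience constructor for chromosome-interval triples used where full CNV
#' records are not needed (region sets, probes in tests).
#'
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive coordinates.
#' @return A `data.table` with columns `chrom`, `start`, `end`.
#' @export
interval <- function(chrom, start, end) {
  if (any(end < start)) stop("end must be >= start")
  data.table(chrom = normalize_chrom(chrom),
             start = as.numeric(start), end = as.numeric(end))
}
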
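# File formats. Native lossless format is TSV with 1-based inclusive
# coordinates; BED (0-based half-open) is converted on read/write; VCF rows
# with SVTYPE=DEL/DUP and INFO END are read as loss/gain over POS+1..END
# (the anchor base at POS is excluded, the structural-variant convention).

#' Pipeline run configuration
#'
#' Single home for every tunable threshold, echoed into outputs for
#' provenance. Defaults: genomic window 100 bp, AF lookup at 70% reciprocal
#' overlap, leakage filter at 50%, 10 Mb length gate, 100x10-fold CV.
#'
#' @param gw genomic window (bp).
#' @param ro_af reciprocal-overlap threshold for AF lookup.
#' @param ro_leak reciprocal-overlap threshold for the leakage filter.
#' @param length_gate maximum modelable CNV length (bp).
#' @param repeats,folds cross-validation schedule.
#' @param seed RNG seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(gw = 100, ro_af = 0.7, ro_leak = 0.5,
                       length_gate = 1e7, repeats = 100, folds = 10,
                       seed = 1) {
  stopifnot(gw >= 0, ro_af > 0, ro_af <= 1, ro_leak > 0, ro_leak <= 1,
            length_gate > 0, repeats >= 1, folds >= 2)
  structure(list(gw = gw, ro_af = ro_af, ro_leak = ro_leak,
                 length_gate = length_gate, repeats = as.integer(repeats),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "run_config")
}

#' Read CNV calls
#'
#' @param path input file.
#' @param format `"tsv"` (columns chrom, start, end, cnv_type and optionally
#'   sample_id, group, label, source, id; 1-based inclusive), `"bed"`
#'   (chrom, start, end, optional 4th column gain/loss; 0-based half-open,
#'   converted on read), or `"vcf"` (SVTYPE=DEL/DUP with INFO END; rows with
#'   other SVTYPEs are skipped with a warning). Guessed from the extension
#'   by default.
#' @return A `cnv_records` table.
#' @export
read_cnvs <- function(path, format = c("auto", "tsv", "bed", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bed = "bed", vcf = "vcf", "tsv")
  }
  if (format == "vcf") return(.read_cnvs_vcf(path))
  dt <- suppressWarnings(fread(path, header = (format == "tsv")))
  if (nrow(dt) == 0) {
    warning("empty CNV file: ", path)
    return(cnv_records(character(0), numeric(0), numeric(0), character(0)))
  }
  if (format == "bed") {
    setnames(dt, seq_len(min(4, ncol(dt))),
             c("chrom", "start", "end", "cnv_type")[seq_len(min(4, ncol(dt)))])
    dt[, start := start + 1]  # 0-based half-open -> 1-based inclusive
    if (!"cnv_type" %in% names(dt)) dt[, cnv_type := "loss"]
  }
  if (any(!is.finite(dt$start)) || any(!is.finite(dt$end)))
    stop("unparseable coordinates in ", path)
  opt <- function(col, default = NA) {
    if (!col %in% names(dt)) return(default)
    v <- as.character(dt[[col]])
    v[!is.na(v) & v == ""] <- NA  # blank cells are absent metadata
    v
  }
  cnv_records(dt$chrom, dt$start, dt$end, dt$cnv_type,
              sample_id = opt("sample_id"), group = opt("group"),
              label = opt("label"), source = opt("source", path),
              id = if ("id" %in% names(dt)) dt$id else NULL)
}

.read_cnvs_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.table(vcfR::getFIX(v))
  if (nrow(fx) == 0) {
    warning("empty VCF: ", path)
    return(cnv_records(character(0), numeric(0), numeric(0), character(0)))
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  end <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  keep <- svtype %in% c("DEL", "DUP")
  if (any(!keep))
    warning(sum(!keep), " VCF row(s) skipped (SVTYPE not DEL/DUP)")
  if (any(keep & !is.finite(end)))
    stop("unparseable END coordinates in ", path)
  pos <- as.numeric(fx$POS)[keep]
  cnv_records(fx$CHROM[keep], pos + 1, end[keep],
              ifelse(svtype[keep] == "DUP", "gain", "loss"),
              source = path)
}

#' Write CNV records
#'
#' @param x a `cnv_records` table.
#' @param path output file.
#' @param format `"tsv"` (lossless, 1-based inclusive) or `"bed"`
#'   (chrom, start-1, end, cnv_type).
#' @export
write_cnvs <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    fwrite(as.data.table(x), path, sep = "\t")
  } else {
    fwrite(data.table(chrom = x$chrom, start = x$start - 1, end = x$end,
                      cnv_type = x$cnv_type),
           path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Write unified CNVs with AF columns
#'
#' @param u a `unified_cnvs` table.
#' @param path output TSV path.
#' @export
write_unified <- function(u, path) {
  fwrite(as.data.table(u), path, sep = "\t")
  invisible(path)
}

#' Read / write an allele-frequency database as TSV
#'
#' Columns: chrom, start, end, cnv_type, af_overall, af_\<GROUP\>...
#'
#' @param path TSV path.
#' @return [read_af_database()] returns an `af_database`.
#' @export
read_af_database <- function(path) {
  af_database(fread(path))
}

#' @rdname read_af_database
#' @param db an `af_database`.
#' @export
write_af_database <- function(db, path) {
  fwrite(as.data.table(db), path, sep = "\t")
  invisible(path)
}

#' Write prediction results
#'
#' One row per input CNV: coordinates, type, length, MVP score (6 decimals),
#' five-tier category, and flags. Gated CNVs (e.g. length > 10 Mb) carry an
#' empty MVP/category and the gate flag.
#'
#' @param records a `cnv_records` table.
#' @param scores MVP scores aligned with `records` (NA where not scored).
#' @param categories categories aligned with `records` (NA where not scored).
#' @param flags character flags aligned with `records` (NA/"" for none).
#' @param path output TSV path.
#' @export
write_predictions <- function(records, scores, categories, flags, path) {
  n <- nrow(records)
  if (length(scores) != n || length(categories) != n || length(flags) != n)
    stop("records, scores, categories and flags must have equal length")
  out <- data.table(chrom = records$chrom, start = records$start,
                    end = records$end, type = records$cnv_type,
                    length = cnv_length(records),
                    MVP = ifelse(is.na(scores), "", sprintf("%.6f", scores)),
                    category = ifelse(is.na(categories), "", categories),
                    flags = ifelse(is.na(flags), "", flags))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an annotation bundle from a JSON manifest
#'
#' The manifest maps annotation names to file paths:
#' `{"tracks": {name: path}, "genes": {...}, "regions": {...},
#'   "cdts_thresholds": {"pct1": x, "pct5": x}}`. Paths are resolved relative
#' to the manifest's directory. Tracks are TSV `chrom pos score`; gene tables
#' TSV `chrom start end gene score`; regions BED (0-based half-open,
#' converted).
#'
#' @param manifest path to the JSON manifest.
#' @return An `xcnv_bundle`.
#' @export
read_bundle <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  rel <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  tracks <- lapply(m$tracks, function(p) fread(rel(p)))
  genes <- lapply(m$genes, function(p) fread(rel(p)))
  regions <- lapply(m$regions, function(p) {
    r <- fread(rel(p), header = FALSE)
    setnames(r, 1:3, c("chrom", "start", "end"))
    r[, start := start + 1]
    r[, .(chrom, start, end)]
  })
  xcnv_bundle(tracks, genes, regions, unlist(m$cdts_thresholds))
}

#' Write an annotation bundle and its manifest
#'
#' @param bundle an `xcnv_bundle`.
#' @param dir output directory (created if needed); the manifest is written
#'   as `manifest.json` inside it.
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- list(tracks = list(), genes = list(), regions = list(),
            cdts_thresholds = as.list(bundle$cdts_thresholds))
  for (nm in names(bundle$tracks)) {
    p <- paste0("track_", nm, ".tsv")
    fwrite(bundle$tracks[[nm]], file.path(dir, p), sep = "\t")
    m$tracks[[nm]] <- p
  }
  for (nm in names(bundle$genes)) {
    p <- paste0("genes_", nm, ".tsv")
    fwrite(bundle$genes[[nm]], file.path(dir, p), sep = "\t")
    m$genes[[nm]] <- p
  }
  for (nm in names(bundle$regions)) {
    p <- paste0("regions_", nm, ".bed")
    r <- bundle$regions[[nm]]
    fwrite(data.table(r$chrom, r$start - 1, r$end), file.path(dir, p),
           sep = "\t", col.names = FALSE)
    m$regions[[nm]] <- p
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(m, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Write / read a feature matrix as TSV
#'
#' The first column `id` holds row names; missing cells are written as NA.
#'
#' @param m an `xcnv_features` matrix.
#' @param path TSV path.
#' @export
write_features <- function(m, path) {
  fwrite(data.table(id = rownames(m), as.data.table(unclass(m))), path,
         sep = "\t")
  invisible(path)
}

#' @rdname write_features
#' @return [read_features()] returns an `xcnv_features` matrix.
#' @export
read_features <- function(path) {
  dt <- fread(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$id
  structure(m, missing = is.na(m), schema = xcnv_feature_schema(),
            class = c("xcnv_features", "matrix", "array"))
}

#' Save / load a fitted model bundle
#'
#' Writes the booster dump plus a JSON sidecar carrying the selected
#' hyperparameters, feature schema, training imputation minima, importances
#' and MVP cutoffs.
#'
#' @param model an `xcnv_model`.
#' @param dir bundle directory (created if needed).
#' @export
save_xcnv_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  meta <- list(selection = model$selection, schema = model$schema,
               minima = as.list(model$minima),
               importance = as.list(model$importance),
               nrounds = model$nrounds, seed = model$seed,
               cutoffs = as.list(model$cutoffs))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_xcnv_model
#' @return [load_xcnv_model()] returns an `xcnv_model`.
#' @export
load_xcnv_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cutoffs <- if (length(meta$cutoffs)) unlist(meta$cutoffs) else NULL
  structure(list(booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
                 selection = as.list(meta$selection),
                 schema = meta$schema, minima = unlist(meta$minima),
                 importance = if (length(meta$importance)) unlist(meta$importance) else NULL,
                 nrounds = meta$nrounds, seed = meta$seed, cutoffs = cutoffs),
            class = "xcnv_model")
}
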
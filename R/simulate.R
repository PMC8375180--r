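# Synthetic-data module: generates a CNV population (true events replicated
# across carrier samples with breakpoint jitter), a matching annotation bundle
# (sparse per-position score tracks, gene tables, cCRE region sets) with
# controllable pathogenicity signal, and five-tier labels from a latent
# linear score with quantile bands. Everything is reproducible from the seed,
# so the whole pipeline is testable without external downloads.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's own
#' tests: a small multi-ethnic cohort, kb-to-Mb CNVs with ~20 bp breakpoint
#' jitter (well inside the 100 bp genomic window), sparse annotation
#' coverage, and a strong pathogenicity signal concentrated in the
#' deleteriousness, conservation, constraint and haploinsufficiency features.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_samples named integer vector of samples per ethnic group.
#' @param n_true_cnvs number of distinct true CNV events.
#' @param len_range log-uniform CNV length bounds (bp).
#' @param gain_frac fraction of gains.
#' @param jitter_sd breakpoint jitter standard deviation (bp); replicate
#'   endpoints are the true endpoints plus rounded Normal(0, jitter_sd) error.
#' @param max_replicates each true CNV is carried by 1..max_replicates
#'   distinct samples (uniform).
#' @param min_separation minimum breakpoint distance enforced between true
#'   CNVs on a chromosome, keeping distinct events distinguishable.
#' @param coverage probability a given track annotates a given CNV at all
#'   (sparse coverage; uncovered cells exercise the imputation path).
#' @param positions_per_cnv mean number of scored positions per covered CNV
#'   per track.
#' @param within_sd score noise around each CNV's per-track latent mean.
#' @param beta named effect-size vector over feature columns; the latent
#'   pathogenicity score is the beta-weighted sum of standardized true
#'   feature values. All zeros = labels independent of features.
#' @param noise_sd latent label noise standard deviation.
#' @param label_bands quantile probabilities of the four band edges splitting
#'   the latent score into the five classes.
#' @param gw genomic window (bp) the downstream unification will use.
#' @param seed RNG seed; fixed seed means byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c("1" = 3e7, "2" = 3e7, "3" = 3e7),
                       n_samples = c(AFR = 20, AMR = 15, ASJ = 5, EAS = 25,
                                     FIN = 5, NFE = 60, SAS = 30, OTH = 10,
                                     UKN = 30),
                       n_true_cnvs = 500,
                       len_range = c(1e3, 1e6),
                       gain_frac = 0.5,
                       jitter_sd = 20,
                       max_replicates = 5,
                       min_separation = 500,
                       coverage = 0.9,
                       positions_per_cnv = 12,
                       within_sd = 0.5,
                       beta = sim_default_beta(),
                       noise_sd = 0.5,
                       label_bands = c(0.30, 0.40, 0.60, 0.70),
                       gw = 100,
                       seed = 1) {
  stopifnot(all(chrom_lengths > 0), all(n_samples > 0), n_true_cnvs > 0,
            jitter_sd >= 0, max_replicates >= 1, coverage >= 0, coverage <= 1,
            length(label_bands) == 4, !is.unsorted(label_bands))
  structure(as.list(environment()), class = "sim_config")
}

#' Default latent effect sizes
#'
#' Positive weights on the deleteriousness aggregates, conservation tracks,
#' constraint fractions, haploinsufficiency scores, regulatory-overlap
#' fractions, gene count and length; zero on type and the PAF columns (allele
#' frequency is an emergent property of replication, not a generative input).
#'
#' @return Named numeric vector over the 30 schema columns.
#' @export
sim_default_beta <- function() {
  s <- xcnv_feature_schema()
  beta <- setNames(numeric(30), s$all)
  beta[c("FATHMM", "LR", "LRT", "MutationAssessor", "MutationTaster",
         "PolyPhen2", "RadialSVM", "SIFT", "VEST3")] <- 0.3
  beta[c("CADD", "GERP", "phyloP100way", "phyloP46way", "SiPhy29way")] <- 0.4
  beta[c("pLI", "Episcore", "GHIS")] <- 0.5
  beta[c("CDTS_pct1", "CDTS_pct5")] <- 0.5
  beta[c("PLS", "pELS", "dELS", "CTCF_bound", "CTCF_only", "DNase_H3K4me3")] <- 0.2
  beta["n_coding_genes"] <- 0.3
  beta["cnv_length"] <- 0.2
  beta
}

#' Simulate a CNV population
#'
#' Draws `n_true_cnvs` true events (placement uniform, lengths log-uniform,
#' breakpoints at least `min_separation` apart within a chromosome), then
#' emits each one from 1..`max_replicates` distinct carrier samples with
#' independent Normal breakpoint jitter (rounded; truncated so start >= 1 and
#' end >= start). The observed-to-true mapping is retained as ground truth.
#'
#' @param cfg a [sim_config()].
#' @return List: `true` (`cnv_records`, ids `true*`), `observed`
#'   (`cnv_records` with sample/group metadata, ids `obs*`), `samples`
#'   (sample_id, group), `group_sizes`, `truth_map` (observed_id, true_id).
#' @export
simulate_cnv_population <- function(cfg) {
  set.seed(cfg$seed)
  samples <- data.table(
    sample_id = sprintf("S%04d", seq_len(sum(cfg$n_samples))),
    group = rep(names(cfg$n_samples), cfg$n_samples)
  )
  chroms <- names(cfg$chrom_lengths)
  placed <- lapply(chroms, function(x) list(s = numeric(0), e = numeric(0)))
  names(placed) <- chroms
  ts <- numeric(cfg$n_true_cnvs); te <- numeric(cfg$n_true_cnvs)
  tc <- character(cfg$n_true_cnvs)
  for (i in seq_len(cfg$n_true_cnvs)) {
    ok <- FALSE
    for (attempt in 1:200) {
      ch <- sample(chroms, 1, prob = cfg$chrom_lengths)
      len <- round(exp(runif(1, log(cfg$len_range[1]), log(cfg$len_range[2]))))
      L <- cfg$chrom_lengths[[ch]]
      if (len > L) next  # longer than the chromosome: redraw
      s <- floor(runif(1, 1, L - len + 1))
      e <- s + len - 1
      p <- placed[[ch]]
      if (length(p$s) == 0 ||
          all(pmax(abs(p$s - s), abs(p$e - e)) >= cfg$min_separation)) {
        placed[[ch]]$s <- c(p$s, s); placed[[ch]]$e <- c(p$e, e)
        ts[i] <- s; te[i] <- e; tc[i] <- ch
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place true CNV ", i,
                  "; reduce n_true_cnvs or min_separation")
  }
  true <- cnv_records(tc, ts, te,
                      ifelse(runif(cfg$n_true_cnvs) < cfg$gain_frac,
                             "gain", "loss"),
                      source = "sim_truth",
                      id = sprintf("true%05d", seq_len(cfg$n_true_cnvs)))
  # replicate across carriers with jitter
  k <- sample(cfg$max_replicates, cfg$n_true_cnvs, replace = TRUE)
  rows <- vector("list", cfg$n_true_cnvs)
  for (i in seq_len(cfg$n_true_cnvs)) {
    carriers <- samples[sample(.N, k[i]), ]
    s <- pmax(1, true$start[i] + round(rnorm(k[i], 0, cfg$jitter_sd)))
    e <- true$end[i] + round(rnorm(k[i], 0, cfg$jitter_sd))
    e <- pmax(e, s)  # truncate so intervals stay valid
    rows[[i]] <- data.table(chrom = true$chrom[i], start = s, end = e,
                            cnv_type = true$cnv_type[i],
                            sample_id = carriers$sample_id,
                            group = carriers$group,
                            true_id = true$id[i])
  }
  obs <- rbindlist(rows)
  observed <- cnv_records(obs$chrom, obs$start, obs$end, obs$cnv_type,
                          sample_id = obs$sample_id, group = obs$group,
                          source = "sim_observed",
                          id = sprintf("obs%06d", seq_len(nrow(obs))))
  list(true = true, observed = observed, samples = samples,
       group_sizes = cfg$n_samples,
       truth_map = data.table(observed_id = observed$id, true_id = obs$true_id))
}

# scored positions for one track over the true CNVs
.sim_track <- function(true, mu, cfg) {
  covered <- runif(nrow(true)) < cfg$coverage
  rows <- lapply(which(covered), function(i) {
    len <- true$end[i] - true$start[i] + 1
    npos <- min(len, 1 + stats::rpois(1, cfg$positions_per_cnv - 1))
    pos <- true$start[i] + sample.int(len, npos) - 1
    data.table(chrom = true$chrom[i], pos = pos,
               score = rnorm(npos, mu[i], cfg$within_sd))
  })
  if (length(rows) == 0)
    return(data.table(chrom = character(0), pos = numeric(0), score = numeric(0)))
  rbindlist(rows)
}

#' Simulate an annotation bundle with known signal
#'
#' Each true CNV gets one latent mean per annotation source; positional track
#' scores scatter around that mean at sparsely sampled positions inside the
#' CNV, gene scores are logistic transforms of it, cCRE coverage fractions
#' follow it, and CDTS positions carry its negation (lower tolerance score =
#' more constrained). The per-source latent means are what the label model
#' ([assign_labels()]) weights, so effect size is controlled by `cfg$beta`.
#' CDTS percentile thresholds are the 1%/5% quantiles of the pooled simulated
#' track.
#'
#' @param cfg a [sim_config()].
#' @param true the true `cnv_records` from [simulate_cnv_population()].
#' @return List: `bundle` (an [xcnv_bundle()]) and `latent` (matrix of
#'   per-CNV per-source latent means, the generative ground truth).
#' @export
simulate_annotation_bundle <- function(cfg, true) {
  set.seed(cfg$seed + 1L)
  n <- nrow(true)
  sources <- c(.snv_tracks(), .gw_tracks(), "CDTS", .gene_tables(), .ccre_sets())
  latent <- matrix(rnorm(n * length(sources)), n,
                   dimnames = list(true$id, sources))
  tracks <- list()
  for (tr in c(.snv_tracks(), .gw_tracks()))
    tracks[[tr]] <- .sim_track(true, latent[, tr], cfg)
  # CDTS: high latent pathogenicity -> low (depleted) tolerance score
  tracks$CDTS <- .sim_track(true, -latent[, "CDTS"], cfg)
  cdts_thresholds <- c(pct1 = unname(quantile(tracks$CDTS$score, 0.01)),
                       pct5 = unname(quantile(tracks$CDTS$score, 0.05)))
  if (nrow(tracks$CDTS) == 0) cdts_thresholds <- c(pct1 = -2.33, pct5 = -1.64)
  # gene tables: 0..3 genes per CNV, scores share the CNV's latent mean
  ngenes <- stats::rpois(n, 1.2)
  gene_rows <- lapply(which(ngenes > 0), function(i) {
    len <- true$end[i] - true$start[i] + 1
    gl <- pmax(50, round(len * runif(ngenes[i], 0.05, 0.3)))
    gs <- true$start[i] + floor(runif(ngenes[i]) * pmax(1, len - gl))
    data.table(chrom = true$chrom[i], start = gs, end = pmin(gs + gl - 1, true$end[i]),
               gene = sprintf("G_%s_%d", true$id[i], seq_len(ngenes[i])),
               cnv = i)
  })
  gene_tbl <- if (length(gene_rows)) rbindlist(gene_rows) else
    data.table(chrom = character(0), start = numeric(0), end = numeric(0),
               gene = character(0), cnv = integer(0))
  genes <- list()
  for (gt in .gene_tables()) {
    g <- copy(gene_tbl)
    g[, score := if (.N) plogis(latent[cnv, gt] + rnorm(.N, 0, 0.3)) else numeric(0)]
    genes[[gt]] <- g[, .(chrom, start, end, gene, score)]
  }
  genes$coding_genes <- gene_tbl[, .(chrom, start, end, gene, score = 1)]
  # cCRE region sets: one interval per CNV covering a latent-driven fraction
  regions <- list()
  for (rs in .ccre_sets()) {
    frac <- plogis(latent[, rs] - 1)
    keep <- runif(n) < 0.8
    rr <- lapply(which(keep), function(i) {
      len <- true$end[i] - true$start[i] + 1
      w <- max(1, round(len * frac[i]))
      s <- true$start[i] + floor(runif(1) * (len - w))
      data.table(chrom = true$chrom[i], start = s, end = s + w - 1)
    })
    regions[[rs]] <- if (length(rr)) rbindlist(rr) else
      data.table(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  list(bundle = xcnv_bundle(tracks, genes, regions, cdts_thresholds),
       latent = latent)
}

#' Assign five-tier labels from a latent linear score
#'
#' The latent pathogenicity score of each true CNV is the beta-weighted sum
#' of its standardized feature values (computed with the package's own
#' feature engine on the simulated bundle, minimum-imputed) plus Normal
#' noise; labels cut the latent score at the four quantile band edges, which
#' are recorded as generative ground truth for cutoff-recovery tests.
#'
#' @param true the true `cnv_records`.
#' @param bundle the simulated `xcnv_bundle`.
#' @param cfg a [sim_config()].
#' @return List: `labels` (five-tier labels aligned with `true` rows),
#'   `latent` (numeric latent scores), `band_edges` (the four cut points).
#' @export
assign_labels <- function(true, bundle, cfg) {
  set.seed(cfg$seed + 2L)
  X <- impute_missing(build_feature_matrix(true, bundle, afdb = NULL))
  Xs <- scale(unclass(X))
  Xs[, attr(Xs, "scaled:scale") == 0 | !is.finite(attr(Xs, "scaled:scale"))] <- 0
  Xs[!is.finite(Xs)] <- 0
  beta <- cfg$beta[colnames(X)]
  beta[is.na(beta)] <- 0
  latent <- drop(Xs %*% beta) + rnorm(nrow(true), 0, cfg$noise_sd)
  edges <- quantile(latent, cfg$label_bands, names = FALSE)
  labels <- xcnv_classes()[findInterval(latent, edges) + 1L]
  list(labels = labels, latent = latent, band_edges = edges)
}

#' Simulate a complete study
#'
#' Convenience wrapper running population, bundle and label generation, then
#' unifying the observed calls at `cfg$gw` and deriving the population AF
#' database from them — every input the modelling pipeline needs.
#'
#' @param cfg a [sim_config()].
#' @return List: `cfg`, `population`, `bundle`, `latent_sources`, `labels`
#'   (on true CNVs), `unified` (observed calls unified, with AF columns),
#'   `afdb`.
#' @export
simulate_xcnv_study <- function(cfg = sim_config()) {
  pop <- simulate_cnv_population(cfg)
  ann <- simulate_annotation_bundle(cfg, pop$true)
  lab <- assign_labels(pop$true, ann$bundle, cfg)
  unified <- unify(pop$observed, gw = cfg$gw, group_sizes = pop$group_sizes)
  afdb <- unified_to_afdb(unified, pop$group_sizes)
  list(cfg = cfg, population = pop, bundle = ann$bundle,
       latent_sources = ann$latent, labels = lab, unified = unified,
       afdb = afdb)
}

#' Map unified CNVs back to true events and labels
#'
#' Each unified CNV inherits the true event backing the majority of its
#' member calls; with the default jitter (well under half the genomic
#' window) cliques are pure and the majority is unanimous.
#'
#' @param unified a `unified_cnvs` table.
#' @param truth_map the `observed_id -> true_id` table from
#'   [simulate_cnv_population()].
#' @param labels five-tier labels aligned with the true CNV table.
#' @param true the true `cnv_records`.
#' @return data.table: one row per unified CNV with `true_id` and `label`.
#' @export
unified_truth <- function(unified, truth_map, labels, true) {
  lab_by_true <- setNames(labels, true$id)
  tm <- setNames(truth_map$true_id, truth_map$observed_id)
  maj <- vapply(strsplit(unified$member_ids, ","), function(ids) {
    tt <- tm[ids]
    names(sort(table(tt), decreasing = TRUE))[1]
  }, character(1))
  data.table(true_id = maj, label = unname(lab_by_true[maj]))
}
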
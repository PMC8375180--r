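# End-to-end synthetic benchmark: the whole pipeline (simulate -> unify ->
# annotate -> gate -> train -> score -> cutoffs -> stratified evaluation) on
# one generated study, with a held-out split for honest AUC.

#' Run the pipeline end to end on a simulated study
#'
#' Generates a study from `cfg`, unifies the observed calls, builds the
#' 30-column feature matrix of the unified CNVs (with AF looked up in the
#' study's own population database), maps labels back through the truth map,
#' trains the classifier on a stratified training split, and evaluates on the
#' held-out remainder. Five-tier cutoffs are derived from the full score set.
#'
#' @param cfg a [sim_config()].
#' @param tune_cfg optional [cv_config()]; when supplied, booster/objective
#'   are selected by cross-validation on the training split, otherwise the
#'   gbtree + binary:logistic default is used.
#' @param test_frac held-out fraction (default 1/3).
#' @return List: `auc` (held-out pathogenic-vs-benign AUC), `cutoffs`,
#'   `report` (held-out stratified metrics), `model`, `tuning` (or NULL),
#'   `scores` (MVP for all unified CNVs), `labels` (five-tier), `study`,
#'   `n_unified`, `test_idx`.
#' @export
run_study_benchmark <- function(cfg = sim_config(), tune_cfg = NULL,
                                test_frac = 1 / 3) {
  study <- simulate_xcnv_study(cfg)
  u <- study$unified
  ur <- cnv_records(u$chrom, u$start, u$end, u$cnv_type,
                    id = sprintf("u%06d", seq_len(nrow(u))))
  gate <- length_gate(ur, max_len = 1e7)
  keep_gate <- match(gate$modelable$id, ur$id)
  ur <- gate$modelable
  X <- build_feature_matrix(ur, study$bundle, study$afdb)
  ut <- unified_truth(u[keep_gate, ], study$population$truth_map,
                      study$labels$labels, study$population$true)
  y <- collapse_labels(ut$label)
  idx <- which(!is.na(y))
  set.seed(cfg$seed + 3L)
  te <- unlist(lapply(split(idx, y[idx]), function(i)
    sample(i, max(1, round(length(i) * test_frac)))))
  tr <- setdiff(idx, te)
  tuning <- NULL
  selection <- list(booster = "gbtree", objective = "binary:logistic")
  if (!is.null(tune_cfg)) {
    tuning <- tune(impute_missing(X[tr, , drop = FALSE]), y[tr], tune_cfg)
    selection <- tuning$selection
  }
  model <- fit_xcnv(X[tr, , drop = FALSE], y[tr], selection, seed = cfg$seed)
  scores <- mvp(model, X)
  auc <- roc_auc(scores[te], y[te])
  cutoffs <- derive_cutoffs(scores, ut$label)
  model$cutoffs <- cutoffs
  report <- stratified_report(ur[te, ], as.integer(scores[te] >= 0.5), y[te])
  list(auc = auc, cutoffs = cutoffs, report = report, model = model,
       tuning = tuning, scores = scores, labels = ut$label, study = study,
       n_unified = nrow(u), test_idx = te)
}
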
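# Gradient-boosted pathogenicity classifier. Booster and objective are the
# two tuned hyperparameters, selected by repeated stratified k-fold
# cross-validation on the median per-repeat AUC; the fitted model's
# probabilistic output is the meta-voting prediction (MVP) score, and four
# sensitivity-specificity-balanced cutoffs map it onto the five ACMG-style
# tiers.

#' Exclude extreme-length CNVs from modelling
#'
#' CNVs longer than 10 Mb are excluded from model development and scoring:
#' they are overwhelmingly pathogenic and would be gated, not predicted.
#'
#' @param cnvs a `cnv_records` table.
#' @param max_len length gate in bp (default 10 Mb).
#' @return List with `modelable` (length <= gate) and `excluded` (with a
#'   `flag` column explaining the exclusion).
#' @export
length_gate <- function(cnvs, max_len = 1e7) {
  long <- cnv_length(cnvs) > max_len
  excluded <- cnvs[long, ]
  if (nrow(excluded))
    excluded[, flag := sprintf("length>%gMb: assumed likely pathogenic, not scored",
                               max_len / 1e6)]
  list(modelable = cnvs[!long, ], excluded = excluded)
}

#' Cross-validation configuration
#'
#' @param boosters candidate boosters, in tie-break preference order.
#' @param objectives candidate learning objectives, in tie-break preference
#'   order.
#' @param repeats number of CV repetitions (default 100).
#' @param folds folds per repetition (default 10).
#' @param seed RNG seed for fold assignment and booster seeding.
#' @param nrounds boosting rounds per CV fit.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(boosters = c("gbtree", "dart", "gblinear"),
                      objectives = c("binary:logistic", "reg:logistic",
                                     "reg:squarederror", "reg:squaredlogerror"),
                      repeats = 100, folds = 10, seed = 1, nrounds = 30) {
  stopifnot(repeats >= 1, folds >= 2, length(boosters) >= 1,
            length(objectives) >= 1)
  structure(list(boosters = boosters, objectives = objectives,
                 repeats = as.integer(repeats), folds = as.integer(folds),
                 seed = as.integer(seed), nrounds = as.integer(nrounds)),
            class = "cv_config")
}

.xgb_params <- function(booster, objective, seed) {
  p <- list(booster = booster, objective = objective, nthread = 1,
            seed = as.integer(seed %% .Machine$integer.max))
  if (booster %in% c("gbtree", "dart")) {
    p$max_depth <- 6; p$eta <- 0.3
  }
  p
}

.xgb_fit <- function(x, y, booster, objective, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = .xgb_params(booster, objective, seed),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

# label-stratified fold assignment: within each class, fold labels are dealt
# round-robin to a random permutation
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Select booster and objective by repeated cross-validation
#'
#' Runs `repeats` repetitions of stratified `folds`-fold cross-validation for
#' every booster x objective combination, records the per-repeat mean
#' held-out AUC, and selects the combination with the highest median; ties
#' break by the declared combination order. Combinations whose objective
#' fails to train on this data (possible for the squared-log-error objective)
#' are dropped with a warning.
#'
#' @param x numeric feature matrix (no missing values; impute first).
#' @param y binary labels, 1 = pathogenic, 0 = benign; both classes required.
#' @param cfg a [cv_config()].
#' @return List of class `xcnv_tuning`: `selection` (booster, objective),
#'   `summary` (data.table with per-combination median/mean/sd of per-repeat
#'   AUCs and the median over all fold-level AUCs), `per_repeat` (matrix of
#'   repeat-level AUCs, combinations x repeats).
#' @export
tune <- function(x, y, cfg = cv_config()) {
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  combos <- data.table(expand.grid(objective = cfg$objectives,
                                   booster = cfg$boosters,
                                   stringsAsFactors = FALSE))[
    , .(booster, objective)]
  setcolorder(combos, c("booster", "objective"))
  # declared order: boosters outer, objectives inner
  combos <- combos[order(match(booster, cfg$boosters),
                         match(objective, cfg$objectives))]
  per_repeat <- matrix(NA_real_, nrow = nrow(combos), ncol = cfg$repeats)
  per_fold_med <- rep(NA_real_, nrow(combos))
  set.seed(cfg$seed)
  fold_sets <- lapply(seq_len(cfg$repeats), function(r) .stratified_folds(y, cfg$folds))
  for (ci in seq_len(nrow(combos))) {
    bo <- combos$booster[ci]; ob <- combos$objective[ci]
    fold_aucs_all <- c()
    for (r in seq_len(cfg$repeats)) {
      fold <- fold_sets[[r]]
      aucs <- rep(NA_real_, cfg$folds)
      for (k in seq_len(cfg$folds)) {
        tr <- fold != k
        if (length(unique(y[!tr])) < 2) next
        bst <- tryCatch(.xgb_fit(x[tr, , drop = FALSE], y[tr], bo, ob,
                                 cfg$nrounds, cfg$seed + r),
                        error = function(e) NULL)
        if (is.null(bst)) next
        p <- tryCatch(predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                        nthread = 1)),
                      error = function(e) NULL)
        if (is.null(p) || any(!is.finite(p))) next
        aucs[k] <- roc_auc(p, y[!tr])
      }
      if (all(is.na(aucs))) { per_repeat[ci, r] <- NA } else {
        per_repeat[ci, r] <- mean(aucs, na.rm = TRUE)
      }
      fold_aucs_all <- c(fold_aucs_all, aucs)
    }
    per_fold_med[ci] <- if (all(is.na(fold_aucs_all))) NA_real_ else
      median(fold_aucs_all, na.rm = TRUE)
  }
  med <- apply(per_repeat, 1, function(v) if (all(is.na(v))) NA_real_ else
    median(v, na.rm = TRUE))
  if (any(is.na(med)))
    warning("dropping combination(s) that failed to train: ",
            paste(combos[is.na(med), paste(booster, objective)], collapse = "; "))
  summary <- copy(combos)
  summary[, median_auc := med]
  summary[, mean_auc := rowMeans(per_repeat, na.rm = TRUE)]
  summary[, sd_auc := apply(per_repeat, 1, sd, na.rm = TRUE)]
  summary[, median_fold_auc := per_fold_med]
  best <- which(med == max(med, na.rm = TRUE))[1]
  structure(list(selection = list(booster = combos$booster[best],
                                  objective = combos$objective[best]),
                 summary = summary, per_repeat = per_repeat),
            class = "xcnv_tuning")
}

#' Fit the pathogenicity classifier
#'
#' Trains the selected booster/objective on the whole training set. Missing
#' feature cells are imputed with the training column minima, which are
#' stored in the model (with the feature schema) so prediction batches are
#' imputed identically.
#'
#' @param features an `xcnv_features` matrix (missing cells allowed).
#' @param y binary labels, 1 = pathogenic, 0 = benign.
#' @param selection list with `booster` and `objective` (e.g. from [tune()]),
#'   default gbtree + binary:logistic.
#' @param nrounds boosting rounds (default 100).
#' @param seed booster RNG seed.
#' @return An `xcnv_model`: fitted booster, selection, `schema` (ordered
#'   feature names), `minima` (training imputation values), normalized
#'   `importance`, and `cutoffs` (NULL until [derive_cutoffs()] output is
#'   attached).
#' @export
fit_xcnv <- function(features, y,
                     selection = list(booster = "gbtree",
                                      objective = "binary:logistic"),
                     nrounds = 100, seed = 1) {
  if (ncol(features) != 30)
    stop("feature matrix must have the 30 schema columns, got ", ncol(features))
  if (length(y) != nrow(features)) stop("labels must align with feature rows")
  minima <- feature_minima(features)
  xi <- impute_missing(features, minima)
  bst <- .xgb_fit(unclass(xi), y, selection$booster, selection$objective,
                  nrounds, seed)
  imp <- tryCatch(xgboost::xgb.importance(model = bst), error = function(e) NULL)
  importance <- NULL
  if (!is.null(imp)) {
    val <- if ("Gain" %in% names(imp)) imp$Gain else abs(imp$Weight)
    importance <- setNames(val / sum(val), imp$Feature)
  }
  structure(list(booster = bst, selection = selection,
                 schema = colnames(features), minima = minima,
                 importance = importance, nrounds = nrounds, seed = seed,
                 cutoffs = NULL),
            class = "xcnv_model")
}

#' Meta-voting prediction (MVP) scores
#'
#' The classifier's probabilistic output in `[0, 1]`; higher = more
#' pathogenic. Regression objectives produce unbounded raw outputs, which are
#' clamped to `[0, 1]` with a warning — the default logistic objectives are
#' already probabilities.
#'
#' @param model an `xcnv_model`.
#' @param features an `xcnv_features` matrix with the model's schema columns;
#'   missing cells are imputed with the training minima.
#' @return Numeric vector of MVP scores in `[0, 1]`.
#' @export
mvp <- function(model, features) {
  if (!all(model$schema %in% colnames(features)))
    stop("feature matrix does not carry the model's schema columns")
  m <- features[, model$schema, drop = FALSE]
  m <- impute_missing(m, model$minima)
  p <- predict(model$booster, xgboost::xgb.DMatrix(unclass(m), nthread = 1))
  if (!grepl("logistic", model$selection$objective) &&
      (any(p < 0) || any(p > 1))) {
    warning("regression objective produced scores outside [0, 1]; clamping")
    p <- pmin(1, pmax(0, p))
  }
  unname(p)
}

#' Derive five-tier MVP cutoffs
#'
#' For each of the four ordered class boundaries
#' (benign | likely_benign | uncertain | likely_pathogenic | pathogenic) the
#' classes above the boundary are positives and the threshold minimizing
#' `|sensitivity - specificity|` over the observed score values is taken
#' (ties toward the smaller threshold, i.e. the more sensitive call). If the
#' four independently derived cutoffs are not monotone they are corrected by
#' isotonic regression, with a warning.
#'
#' @param scores MVP scores in `[0, 1]`.
#' @param labels5 five-tier labels; all five classes must be present.
#' @return Named numeric vector `c(c_benign, c_lben, c_unc, c_path)`.
#' @export
derive_cutoffs <- function(scores, labels5) {
  classes <- xcnv_classes()
  missing_cl <- setdiff(classes, unique(labels5))
  if (length(missing_cl))
    stop("label class(es) absent: ", paste(missing_cl, collapse = ", "))
  cand <- sort(unique(scores))
  cuts <- vapply(1:4, function(k) {
    pos <- labels5 %in% classes[(k + 1):5]
    sp <- scores[pos]; sn <- scores[!pos]
    gap <- vapply(cand, function(t) abs(mean(sp >= t) - mean(sn < t)), numeric(1))
    cand[which.min(gap)]  # which.min takes the first (smallest) on ties
  }, numeric(1))
  if (any(diff(cuts) < 0)) {
    warning("derived cutoffs were not monotone; applying isotonic correction")
    cuts <- stats::isoreg(1:4, cuts)$yf
  }
  setNames(cuts, c("c_benign", "c_lben", "c_unc", "c_path"))
}

#' Assign pathogenicity categories from MVP scores
#'
#' With cutoffs `(c_benign, c_lben, c_unc, c_path)`: benign below `c_benign`;
#' likely benign in `[c_benign, c_lben)`; uncertain in `[c_lben, c_unc)`;
#' likely pathogenic in `[c_unc, c_path]`; pathogenic above `c_path`. At the
#' published cutoffs `(0.14, 0.16, 0.46, 0.76)` a score of 0.90 is
#' pathogenic and 0.10 benign.
#'
#' @param scores MVP scores in `[0, 1]`.
#' @param cutoffs named or plain numeric vector of 4 nondecreasing cutoffs.
#' @return Character vector of the five class labels.
#' @export
categorize <- function(scores, cutoffs) {
  if (any(scores < 0 | scores > 1 | !is.finite(scores)))
    stop("MVP scores must lie in [0, 1]")
  if (length(cutoffs) != 4 || any(diff(cutoffs) < 0))
    stop("cutoffs must be 4 nondecreasing values")
  cl <- xcnv_classes()
  ifelse(scores < cutoffs[1], cl[1],
  ifelse(scores < cutoffs[2], cl[2],
  ifelse(scores < cutoffs[3], cl[3],
  ifelse(scores <= cutoffs[4], cl[4], cl[5]))))
}
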
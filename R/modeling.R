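# Subpart-by-horizon gradient-boosted submodels, randomized hyperparameter
# search, comparators, out-of-fold stacking and the meta-predictor.
#
# The central fitting function is fit_progression_stack(): it freezes every
# data-dependent quantity (medication offsets, imputation values, scaler,
# per-model feature lists, tuned parameters, models) on the training cohort
# and exposes a predict() method that applies them unchanged to an external
# cohort.

#' Stratified train/test split of labelled subjects
#'
#' Splits within each label stratum so progressor prevalence is preserved
#' on both sides (proportional allocation keeps the difference well within
#' 0.03 of the parent for the cohort sizes used here).
#'
#' @param labels named logical vector (names = subject ids).
#' @param frac training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, frac = 0.75, seed = 1) {
  stopifnot(!is.null(names(labels)), !anyNA(labels))
  if (min(table(labels)) < 2L) {
    config_error("each label class needs at least 2 members to split")
  }
  set.seed(seed)
  train <- character(0)
  for (cl in c(FALSE, TRUE)) {
    ids <- names(labels)[labels == cl]
    n_tr <- round(length(ids) * frac)
    train <- c(train, sample(ids, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(names(labels), train)))
}

#' Randomized hyperparameter search space
#'
#' The tunable ranges of the boosted (DART) submodels: `lambda`, `alpha`,
#' `eta`, `gamma`, `rate_drop`, `skip_drop` log-uniform on \[1e-8, 1\];
#' `subsample`, `colsample_bytree` uniform on \[0.5, 1\];
#' `scale_pos_weight` uniform on \[0.8, 1.2\]; `max_depth` uniform integer
#' on \[6, 36\]; `min_child_weight` uniform on \[1, 10\]; `grow_policy` in
#' {depthwise, lossguide}; `sample_type` in {uniform, weighted};
#' `normalize_type` in {tree, forest}.
#'
#' @return list of class `search_space` describing each dimension.
#' @export
default_search_space <- function() {
  structure(list(
    lambda = c(1e-8, 1), alpha = c(1e-8, 1), eta = c(1e-8, 1),
    gamma = c(1e-8, 1), rate_drop = c(1e-8, 1), skip_drop = c(1e-8, 1),
    subsample = c(0.5, 1), colsample_bytree = c(0.5, 1),
    scale_pos_weight = c(0.8, 1.2), max_depth = c(6L, 36L),
    min_child_weight = c(1, 10),
    grow_policy = c("depthwise", "lossguide"),
    sample_type = c("uniform", "weighted"),
    normalize_type = c("tree", "forest")
  ), class = "search_space")
}

LOG_UNIFORM <- c("lambda", "alpha", "eta", "gamma", "rate_drop", "skip_drop")

#' Draw random hyperparameter configurations
#'
#' Regularization and rate parameters are sampled log-uniformly, bounded
#' numeric parameters uniformly, integer and categorical parameters
#' uniformly over their values.
#'
#' @param n_trials number of configurations.
#' @param seed integer seed.
#' @param space a [default_search_space()].
#' @return list of parameter lists.
#' @export
sample_params <- function(n_trials, seed = 1, space = default_search_space()) {
  if (n_trials < 1) config_error("n_trials must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    p <- list()
    for (nm in names(space)) {
      rng <- space[[nm]]
      p[[nm]] <- if (is.character(rng)) {
        sample(rng, 1)
      } else if (nm == "max_depth") {
        sample(seq(rng[1], rng[2]), 1)
      } else if (nm %in% LOG_UNIFORM) {
        exp(stats::runif(1, log(rng[1]), log(rng[2])))
      } else {
        stats::runif(1, rng[1], rng[2])
      }
    }
    p
  })
}

f1_at <- function(y, prob, threshold = 0.5) {
  pred <- prob > threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0); fn <- sum(!pred & y == 1)
  if (tp == 0) return(0)
  pr <- tp / (tp + fp); rc <- tp / (tp + fn)
  2 * pr * rc / (pr + rc)
}

# fit one boosted classifier; params from the search space ride on top of
# the fixed objective/booster settings
fit_xgb <- function(X, y, params, nrounds = 150, seed = 1,
                    Xval = NULL, yval = NULL, early_stopping = 10) {
  X <- feature_matrix(as.data.frame(X))
  base <- list(objective = "binary:logistic", booster = "dart",
               nthread = 1, seed = seed)
  d <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  args <- list(params = c(base, params), data = d, nrounds = nrounds,
               verbose = 0)
  if (!is.null(Xval)) {
    dv <- xgboost::xgb.DMatrix(feature_matrix(as.data.frame(Xval)),
                               label = as.numeric(yval))
    args$evals <- list(val = dv)
    args$early_stopping_rounds <- early_stopping
  }
  do.call(xgboost::xgb.train, args)
}

#' Tune one submodel by randomized search
#'
#' Draws `n_trials` configurations from the search space, fits each on the
#' training rows and keeps the configuration with the best validation F1
#' (threshold 0.5; ties keep the earliest trial). Reproducible given the
#' seed.
#'
#' @param Xtr,ytr training features and 0/1 labels.
#' @param Xval,yval disjoint validation features and labels.
#' @param n_trials number of random draws (>= 1).
#' @param seed integer seed.
#' @param nrounds maximum boosting rounds (early stopping on validation
#'   loss).
#' @param space a [default_search_space()].
#' @param objective model-selection criterion: validation F1 at threshold
#'   0.5 (submodels) or validation ROC AUC (meta level, whose reported
#'   headline metric is AUC).
#' @return list with `model` (the best configuration's fit on the training
#'   rows), `params`, `val_f1`, `val_auc`, `trials` (per-trial scores),
#'   `nrounds` (early-stopped round count).
#' @export
tune_submodel <- function(Xtr, ytr, Xval, yval, n_trials = 25, seed = 1,
                          nrounds = 150, space = default_search_space(),
                          objective = c("f1", "auc")) {
  objective <- match.arg(objective)
  draws <- sample_params(n_trials, seed = seed, space = space)
  score <- numeric(n_trials)
  f1s <- numeric(n_trials)
  degenerate <- logical(n_trials)
  models <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    m <- fit_xgb(Xtr, ytr, draws[[i]], nrounds = nrounds,
                 seed = stage_seed(seed, i), Xval = Xval, yval = yval)
    prob <- stats::predict(m, feature_matrix(as.data.frame(Xval)))
    f1s[i] <- f1_at(as.numeric(yval), prob)
    score[i] <- if (objective == "f1") f1s[i] else roc_auc(yval, prob)
    # a configuration that assigns every validation subject to one class
    # has no discriminative content; prefer any non-degenerate trial
    degenerate[i] <- length(unique(prob > 0.5)) < 2L
    models[[i]] <- m
  }
  cand <- if (all(degenerate)) seq_len(n_trials) else which(!degenerate)
  best_i <- cand[which.max(score[cand])]
  best_model <- models[[best_i]]
  bi <- xgboost::xgb.attributes(best_model)$best_iteration
  best_nrounds <- if (is.null(bi)) nrounds else max(1L, as.integer(bi))
  list(model = best_model, params = draws[[best_i]], val_f1 = f1s[best_i],
       val_auc = if (objective == "auc") score[best_i] else NA_real_,
       trials = score, trial = best_i, nrounds = best_nrounds)
}

# randomized search scored by pooled K-fold cross-validated AUC: one
# stratified fold assignment is shared by all trials; each draw is refit
# per fold and scored on its pooled out-of-fold predictions. Lower-variance
# selection than a single 75/25 split; used for the meta level.
tune_cv <- function(X, y, n_trials, seed, nrounds, n_folds = 5,
                    space = default_search_space()) {
  ids <- names(y)
  Xm <- feature_matrix(as.data.frame(X))
  draws <- sample_params(n_trials, seed = seed, space = space)
  fold <- integer(length(y)); names(fold) <- ids
  set.seed(stage_seed(seed, 7))
  for (cl in c(FALSE, TRUE)) {
    cid <- sample(ids[y == cl])
    fold[cid] <- rep_len(seq_len(n_folds), length(cid))
  }
  aucs <- numeric(n_trials)
  iters <- numeric(n_trials)
  f1s <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    oof <- rep(NA_real_, length(y))
    it <- integer(0)
    for (k in seq_len(n_folds)) {
      tr <- fold != k; te <- fold == k
      if (length(unique(y[tr])) < 2L) next
      mk <- fit_xgb(Xm[tr, , drop = FALSE], y[tr], draws[[i]],
                    nrounds = nrounds, seed = stage_seed(seed, 20 + k),
                    Xval = Xm[te, , drop = FALSE], yval = y[te])
    bi <- xgboost::xgb.attributes(mk)$best_iteration
      it <- c(it, if (is.null(bi)) nrounds else as.integer(bi))
      oof[te] <- stats::predict(mk, Xm[te, , drop = FALSE])
    }
    ok <- !is.na(oof)
    aucs[i] <- roc_auc(y[ok], oof[ok])
    f1s[i] <- f1_at(as.numeric(y[ok]), oof[ok])
    iters[i] <- max(1L, round(mean(it)))
  }
  best_i <- which.max(aucs)
  list(params = draws[[best_i]], val_f1 = f1s[best_i],
       val_auc = aucs[best_i], trials = aucs, trial = best_i,
       nrounds = iters[best_i])
}

# guard: the label (or anything perfectly identical to it) must never sit
# in the feature table
check_no_leak <- function(X, y) {
  for (nm in colnames(X)) {
    x <- as.numeric(X[, nm])
    if (stats::sd(x) > 0 && length(unique(x)) <= 2 &&
        all((x == max(x)) == (as.numeric(y) == 1))) {
      config_error("feature '%s' is identical to the label: leaked outcome",
                   nm)
    }
  }
  invisible(TRUE)
}

# train one target: explainer-driven feature selection on an internal
# 75/25 split, randomized tuning, final refit on all labelled rows (at the
# early-stopped round count), plus out-of-fold probabilities for stacking
train_one_target <- function(X, y, top_k, n_trials, n_folds, nrounds,
                             seed, objective = "f1", cv_tune = FALSE) {
  ids <- names(y)
  Xm <- feature_matrix(X[ids, , drop = FALSE])
  check_no_leak(Xm, y)
  sp <- stratified_split(y, 0.75, seed = stage_seed(seed, 1))
  expl <- fit_explainer(Xm[sp$train, , drop = FALSE], y[sp$train],
                        seed = stage_seed(seed, 2))
  ranking <- rank_features(expl, Xm[sp$train, , drop = FALSE])
  feats <- select_top(ranking, top_k)
  tuned <- if (cv_tune) {
    tune_cv(Xm[, feats, drop = FALSE], y, n_trials = n_trials,
            seed = stage_seed(seed, 3), nrounds = nrounds,
            n_folds = n_folds)
  } else {
    tune_submodel(Xm[sp$train, feats, drop = FALSE], y[sp$train],
                  Xm[sp$test, feats, drop = FALSE], y[sp$test],
                  n_trials = n_trials, seed = stage_seed(seed, 3),
                  nrounds = nrounds, objective = objective)
  }
  nrounds <- tuned$nrounds
  final <- fit_xgb(Xm[, feats, drop = FALSE], y, tuned$params,
                   nrounds = nrounds, seed = stage_seed(seed, 4))
  # out-of-fold probabilities: each training subject is predicted by a
  # model whose folds excluded it
  oof <- rep(NA_real_, length(y)); names(oof) <- ids
  fold <- integer(length(y)); names(fold) <- ids
  fold_models <- vector("list", n_folds)
  set.seed(stage_seed(seed, 5))
  for (cl in c(FALSE, TRUE)) {
    cid <- sample(ids[y == cl])
    fold[cid] <- rep_len(seq_len(n_folds), length(cid))
  }
  for (k in seq_len(n_folds)) {
    tr <- ids[fold != k]; te <- ids[fold == k]
    if (length(te) == 0L || length(unique(y[tr])) < 2L) next
    mk <- fit_xgb(Xm[tr, feats, drop = FALSE], y[tr], tuned$params,
                  nrounds = nrounds, seed = stage_seed(seed, 100 + k))
    oof[te] <- stats::predict(mk, Xm[te, feats, drop = FALSE])
    fold_models[[k]] <- mk
  }
  list(model = final, params = tuned$params, features = feats,
       ranking = ranking, val_f1 = tuned$val_f1, oof = oof, fold = fold,
       fold_models = fold_models, n = length(y), prevalence = mean(y))
}

#' Fit the stacked progression meta-predictor
#'
#' The full training path on one cohort: medication-adjustment offsets are
#' estimated and applied; subjects are labelled for every subpart x
#' horizon target; baseline features (plus polygenic scores and monogenic
#' flags when genotypes are supplied) are filtered for missingness,
#' imputed, and standardized; nine subpart submodels (MDS-UPDRS I/II/III x
#' 12/24/36 months) and three direct Total models are feature-selected by
#' Shapley attribution and tuned by randomized search; the nine submodels'
#' out-of-fold probabilities are joined to the baseline features and a
#' tuned meta-model predicts Total progression at the target horizon.
#'
#' Out-of-fold stacking means no training subject's meta-feature was
#' produced by a model that saw that subject; external cohorts get
#' submodel probabilities from the full-training-cohort submodels.
#'
#' @param cohort training `pd_cohort`.
#' @param geno optional [genotype_data()] for the same subjects.
#' @param weights_pd,weights_ea [weight_table()]s (used when `geno` is
#'   given).
#' @param carriers optional monogenic carrier calls.
#' @param target_horizon horizon (months) of the primary Total
#'   meta-prediction (the one `predict()` and [evaluate_stack()] report).
#' @param meta_horizons horizons for which meta-models are fitted;
#'   defaults to just `target_horizon`.
#' @param horizons submodel horizons.
#' @param top_k features kept per model.
#' @param n_trials randomized-search draws per model.
#' @param n_folds stacking folds.
#' @param nrounds maximum boosting rounds.
#' @param include_items,exclude_ess passed to [build_features()].
#' @param drop_class optional feature class to ablate (see [ablate()]).
#' @param seed integer seed; the whole path is reproducible from it.
#' @return object of class `prog_stack`.
#' @export
fit_progression_stack <- function(cohort, geno = NULL, weights_pd = NULL,
                                  weights_ea = NULL, carriers = NULL,
                                  target_horizon = 12,
                                  meta_horizons = target_horizon,
                                  horizons = c(12, 24, 36),
                                  top_k = 25, n_trials = 25, n_folds = 5,
                                  nrounds = 150, include_items = TRUE,
                                  exclude_ess = TRUE, drop_class = NULL,
                                  submodel_predict = c("fold_average",
                                                       "full"),
                                  seed = 1) {
  submodel_predict <- match.arg(submodel_predict)
  stopifnot(inherits(cohort, "pd_cohort"))
  stopifnot(target_horizon %in% horizons,
            all(meta_horizons %in% horizons),
            target_horizon %in% meta_horizons)
  offsets <- estimate_offsets(cohort)
  adj <- apply_adjustment(cohort, offsets)
  labels <- label_progression(adj, horizons = horizons)

  prs_pd <- if (!is.null(geno)) compute_prs(geno, weights_pd) else NULL
  prs_ea <- if (!is.null(geno)) compute_prs(geno, weights_ea) else NULL
  X <- build_features(adj, prs_pd = prs_pd, prs_ea = prs_ea,
                      carriers = carriers, include_items = include_items,
                      exclude_ess = exclude_ess)
  X <- drop_high_missingness(X, 0.5)
  dropped <- attr(X, "dropped")
  schema <- attr(X, "schema")
  if (!is.null(drop_class)) {
    if (!drop_class %in% FEATURE_CLASSES) {
      config_error("unknown feature class '%s'", drop_class)
    }
    gone <- schema$class == drop_class
    if (!any(gone)) {
      warning(sprintf("no '%s' features present: ablation is a no-op",
                      drop_class))
    }
    X <- X[, !gone, drop = FALSE]
    schema <- schema[!gone, , drop = FALSE]
  }
  imputer <- fit_imputer(X, schema)
  X <- apply_imputer(X, imputer)
  scaler <- fit_scaler(X)
  X <- apply_scaler(X, scaler)

  submodels <- list(); direct <- list()
  tgt_i <- 0L
  for (p in PARTS) {
    for (h in horizons) {
      tgt_i <- tgt_i + 1L
      y <- label_vector(labels, p, h)
      key <- sprintf("%s_%d", p, h)
      if (length(unique(y)) < 2L) {
        warning(sprintf("target %s has a single class: submodel skipped", key))
        next
      }
      submodels[[key]] <- train_one_target(
        X, y, top_k, n_trials, n_folds, nrounds,
        seed = stage_seed(seed, 1000 + tgt_i))
    }
  }
  for (h in horizons) {
    y <- label_vector(labels, "Total", h)
    key <- sprintf("Total_%d", h)
    if (length(unique(y)) < 2L) {
      warning(sprintf("target %s has a single class: direct model skipped", key))
      next
    }
    direct[[key]] <- train_one_target(
      X, y, top_k, n_trials, n_folds, nrounds,
      seed = stage_seed(seed, 2000 + h))
  }

  # meta tables: nine out-of-fold submodel probabilities + the selected
  # baseline features (those chosen for the direct Total model at the
  # same horizon), re-selected and tuned at the meta level. The meta
  # table is narrow, so its randomized search is cheap: it gets a deeper,
  # cross-validated search to stabilize the stacked layer.
  metas <- list()
  for (h in meta_horizons) {
    key_h <- sprintf("Total_%d", h)
    y_meta <- label_vector(labels, "Total", h)
    base_feats <- direct[[key_h]]$features
    if (is.null(base_feats)) base_feats <- colnames(X)
    meta_X <- X[names(y_meta), base_feats, drop = FALSE]
    for (key in names(submodels)) {
      meta_X[[paste0("p_", key)]] <- submodels[[key]]$oof[rownames(meta_X)]
    }
    prob_cols <- paste0("p_", names(submodels))
    complete <- stats::complete.cases(meta_X[, prob_cols, drop = FALSE])
    metas[[key_h]] <- train_one_target(
      meta_X[complete, , drop = FALSE],
      y_meta[rownames(meta_X)[complete]], top_k, 2L * n_trials,
      n_folds, nrounds, seed = stage_seed(seed, 3000 + h),
      objective = "auc", cv_tune = TRUE)
  }
  meta <- metas[[sprintf("Total_%d", target_horizon)]]

  structure(list(
    offsets = offsets, imputer = imputer, scaler = scaler,
    schema = schema, dropped_features = dropped,
    submodels = submodels, direct = direct, meta = meta, metas = metas,
    labels = labels, target_horizon = target_horizon,
    horizons = horizons, drop_class = drop_class,
    submodel_predict = submodel_predict,
    include_items = include_items, exclude_ess = exclude_ess,
    top_k = top_k, n_trials = n_trials, n_folds = n_folds,
    nrounds = nrounds, seed = seed,
    n_train = nrow(X), call = match.call()
  ), class = "prog_stack")
}

# frozen transform path shared by predict(): adjust, featurize, impute,
# scale with training-cohort parameters only
transform_cohort <- function(object, cohort, geno = NULL, weights_pd = NULL,
                             weights_ea = NULL, carriers = NULL) {
  adj <- apply_adjustment(cohort, object$offsets)
  prs_pd <- if (!is.null(geno)) compute_prs(geno, weights_pd) else NULL
  prs_ea <- if (!is.null(geno)) compute_prs(geno, weights_ea) else NULL
  X <- build_features(adj, prs_pd = prs_pd, prs_ea = prs_ea,
                      carriers = carriers,
                      include_items = object$include_items,
                      exclude_ess = object$exclude_ess)
  # columns are dictated by the training schema: missing ones (e.g.
  # imaging in an imaging-free cohort) are created as NA and imputed with
  # training values
  for (nm in setdiff(object$schema$column, names(X))) X[[nm]] <- NA_real_
  X <- X[, object$schema$column, drop = FALSE]
  X <- apply_imputer(X, object$imputer)
  X <- apply_scaler(X, object$scaler)
  list(X = X, adj = adj)
}

#' Predict progression probabilities for a cohort
#'
#' Applies the frozen training-cohort transforms and models: submodel
#' probabilities come from the submodels fitted on the full training
#' cohort, and feed the meta-model together with the baseline features.
#'
#' @param object a `prog_stack`.
#' @param cohort a `pd_cohort` to predict for (external test cohort or the
#'   training cohort itself).
#' @param geno,weights_pd,weights_ea,carriers genetic inputs as in
#'   [fit_progression_stack()].
#' @param ... unused.
#' @return data.frame with `subject_id`, the nine submodel probabilities
#'   (`p_I_12`, ...), `direct_prob` (direct Total model at the target
#'   horizon) and `meta_prob`.
#' @export
predict.prog_stack <- function(object, cohort, geno = NULL,
                               weights_pd = NULL, weights_ea = NULL,
                               carriers = NULL, ...) {
  tf <- transform_cohort(object, cohort, geno, weights_pd, weights_ea,
                         carriers)
  X <- tf$X
  out <- data.frame(subject_id = rownames(X), stringsAsFactors = FALSE)
  submodel_prob <- function(sm) {
    Xs <- feature_matrix(X[, sm$features, drop = FALSE])
    if (identical(object$submodel_predict, "full")) {
      stats::predict(sm$model, Xs)
    } else {
      # average of the stacking fold models: matches the out-of-fold
      # probability distribution the meta-model was trained on
      ok <- !vapply(sm$fold_models, is.null, logical(1))
      rowMeans(vapply(sm$fold_models[ok],
                      function(m) stats::predict(m, Xs),
                      numeric(nrow(Xs))))
    }
  }
  for (key in names(object$submodels)) {
    out[[paste0("p_", key)]] <- submodel_prob(object$submodels[[key]])
  }
  dkey <- sprintf("Total_%d", object$target_horizon)
  dm <- object$direct[[dkey]]
  if (!is.null(dm)) {
    out$direct_prob <-
      stats::predict(dm$model,
                     feature_matrix(X[, dm$features, drop = FALSE]))
  }
  meta_X <- X
  for (key in names(object$submodels)) {
    meta_X[[paste0("p_", key)]] <- out[[paste0("p_", key)]]
  }
  out$meta_prob <-
    stats::predict(object$meta$model,
                   feature_matrix(meta_X[, object$meta$features,
                                         drop = FALSE]))
  out
}

#' Evaluate a fitted stack on a cohort
#'
#' Labels the cohort (with the frozen offsets, whose constant shift cannot
#' change any label) and scores the meta and direct predictions of Total
#' progression at the target horizon.
#'
#' @param object a `prog_stack`.
#' @param cohort,geno,weights_pd,weights_ea,carriers evaluation inputs.
#' @param subjects optional subject ids to restrict to (e.g. a held-out
#'   test split).
#' @return list with `meta` and `direct` [classification_metrics()]
#'   entries, plus `predictions` and `labels`.
#' @export
evaluate_stack <- function(object, cohort, geno = NULL, weights_pd = NULL,
                           weights_ea = NULL, carriers = NULL,
                           subjects = NULL) {
  preds <- stats::predict(object, cohort, geno, weights_pd, weights_ea,
                          carriers)
  labels <- label_progression(apply_adjustment(cohort, object$offsets),
                              horizons = object$horizons)
  y <- label_vector(labels, "Total", object$target_horizon)
  if (!is.null(subjects)) y <- y[names(y) %in% subjects]
  idx <- match(names(y), preds$subject_id)
  ok <- !is.na(idx)
  y <- y[ok]; idx <- idx[ok]
  list(meta = classification_metrics(y, preds$meta_prob[idx]),
       direct = if (!is.null(preds$direct_prob))
         classification_metrics(y, preds$direct_prob[idx]) else NULL,
       predictions = preds[idx, ], labels = labels, y = y)
}

#' Feature-class ablation of the stacked pipeline
#'
#' Removes every feature of one class (genetic, physician-exam, survey,
#' imaging) and refits the entire pipeline from feature selection onward;
#' submodel meta-features are rebuilt from the reduced feature set.
#' Dropping a class absent from the cohort (e.g. imaging in a PDBP-like
#' cohort) is a no-op with a warning.
#'
#' @param cohort,geno,weights_pd,weights_ea,carriers training inputs as in
#'   [fit_progression_stack()].
#' @param drop_class class to remove.
#' @param ... further arguments to [fit_progression_stack()].
#' @return the refitted `prog_stack`.
#' @export
ablate <- function(cohort, geno = NULL, weights_pd = NULL,
                   weights_ea = NULL, carriers = NULL,
                   drop_class = c("genetic", "physician-exam", "survey",
                                  "imaging"), ...) {
  drop_class <- match.arg(drop_class)
  fit_progression_stack(cohort, geno, weights_pd, weights_ea, carriers,
                        drop_class = drop_class, ...)
}

#' Comparator classifiers: logistic regression and balanced random forest
#'
#' Baselines for the boosted submodels: an unpenalized logistic regression
#' and a random forest with per-class balanced bootstrap sampling
#' (each tree draws equally from both classes).
#'
#' @param Xtr,ytr training features (data.frame/matrix) and 0/1 labels.
#' @param Xte,yte evaluation features and labels.
#' @param seed integer seed.
#' @param ntree forest size.
#' @return list with `lr` and `brf` sublists (`model`, `prob`, `f1`).
#' @export
comparator_models <- function(Xtr, ytr, Xte, yte, seed = 1, ntree = 300) {
  Xtr <- as.data.frame(Xtr); Xte <- as.data.frame(Xte)
  ytr <- as.numeric(ytr); yte <- as.numeric(yte)
  set.seed(seed)
  dtr <- cbind(.y = ytr, Xtr)
  lr <- suppressWarnings(stats::glm(.y ~ ., data = dtr,
                                    family = stats::binomial()))
  p_lr <- suppressWarnings(
    stats::predict(lr, newdata = Xte, type = "response"))
  yf <- factor(ytr, levels = c(0, 1))
  nmin <- min(table(yf))
  brf <- randomForest::randomForest(
    x = Xtr, y = yf, ntree = ntree, strata = yf,
    sampsize = c(nmin, nmin))
  p_brf <- stats::predict(brf, newdata = Xte, type = "prob")[, "1"]
  list(lr = list(model = lr, prob = p_lr, f1 = f1_at(yte, p_lr)),
       brf = list(model = brf, prob = p_brf, f1 = f1_at(yte, p_brf)))
}

#' @export
print.prog_stack <- function(x, ...) {
  cat("Stacked progression meta-predictor (prog_stack)\n")
  cat(sprintf("  training subjects: %d; target: %d-month MDS-UPDRS Total\n",
              x$n_train, x$target_horizon))
  if (!is.null(x$drop_class)) {
    cat(sprintf("  ablated feature class: %s\n", x$drop_class))
  }
  cat(sprintf("  submodels: %s\n", paste(names(x$submodels), collapse = " ")))
  cat(sprintf("  meta validation F1 = %.3f (internal split)\n",
              x$meta$val_f1))
  invisible(x)
}

#' @export
summary.prog_stack <- function(object, ...) {
  sub_tab <- do.call(rbind, lapply(names(object$submodels), function(k) {
    s <- object$submodels[[k]]
    data.frame(target = k, n = s$n, prevalence = round(s$prevalence, 3),
               val_f1 = round(s$val_f1, 3), stringsAsFactors = FALSE)
  }))
  dir_tab <- do.call(rbind, lapply(names(object$direct), function(k) {
    s <- object$direct[[k]]
    data.frame(target = k, n = s$n, prevalence = round(s$prevalence, 3),
               val_f1 = round(s$val_f1, 3), stringsAsFactors = FALSE)
  }))
  out <- list(submodels = sub_tab, direct = dir_tab,
              meta_val_f1 = object$meta$val_f1,
              meta_features = object$meta$features,
              offsets = object$offsets)
  class(out) <- "summary.prog_stack"
  out
}

#' @export
print.summary.prog_stack <- function(x, ...) {
  cat("Subpart x horizon submodels (internal validation F1):\n")
  print(x$submodels, row.names = FALSE)
  cat("Direct Total models:\n")
  print(x$direct, row.names = FALSE)
  cat(sprintf("Meta-model validation F1: %.3f\n", x$meta_val_f1))
  cat("Top meta-features:\n  ")
  cat(paste(utils::head(x$meta_features, 10), collapse = ", "), "\n")
  print(x$offsets)
  invisible(x)
}

#' ROC curve of the stacked prediction on a cohort
#'
#' @param x a `prog_stack`.
#' @param cohort,geno,weights_pd,weights_ea,carriers evaluation inputs as
#'   in [evaluate_stack()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the evaluation list.
#' @export
plot.prog_stack <- function(x, cohort, geno = NULL, weights_pd = NULL,
                            weights_ea = NULL, carriers = NULL, ...) {
  ev <- evaluate_stack(x, cohort, geno, weights_pd, weights_ea, carriers)
  y <- as.integer(ev$y)
  prob <- ev$predictions$meta_prob
  ord <- order(prob, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y[ord] == 0) / sum(y == 0))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Meta-prediction ROC (AUC = %.3f)",
                                ev$meta$roc_auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(ev)
}
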
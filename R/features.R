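# Feature engineering: baseline feature assembly, missingness filtering,
# typed imputation, train-anchored standardization and Shapley-value
# feature ranking.
#
# Every transform (imputation values, scaler means/SDs, dropped columns,
# selected feature lists) is fitted on training-cohort rows only and
# applied frozen to any other cohort.

FEATURE_CLASSES <- c("genetic", "physician-exam", "survey", "imaging",
                     "demographic")

# pattern rules mapping column names to (type, class); the Total score is
# tagged physician-exam since the motor exam dominates its range
schema_rules <- function() {
  list(
    list("^age$", "continuous", "demographic"),
    list("^sex$", "categorical", "demographic"),
    list("^education_years$", "ordinal", "demographic"),
    list("^updrs1(_\\d+)?$", "ordinal", "survey"),
    list("^updrs2(_\\d+)?$", "ordinal", "survey"),
    list("^updrs3(_\\d+)?$", "ordinal", "physician-exam"),
    list("^updrs_total$", "continuous", "physician-exam"),
    list("^moca$", "ordinal", "survey"),
    list("^seadl$", "ordinal", "survey"),
    list("^ess$", "ordinal", "survey"),
    list("^hoehn_yahr$", "ordinal", "physician-exam"),
    list("^sbr_", "continuous", "imaging"),
    list("^prs_", "continuous", "genetic"),
    list("^(GBA|LRRK2|SNCA|monogenic_any)$", "categorical", "genetic")
  )
}

#' Typed schema for a set of feature columns
#'
#' Assigns each feature column a value type (continuous / ordinal /
#' categorical, driving the imputation rule) and a feature class
#' (genetic / physician-exam / survey / imaging / demographic, driving
#' ablation).
#'
#' @param columns character vector of feature names.
#' @return data.frame with `column`, `type`, `class`.
#' @export
feature_schema <- function(columns) {
  rules <- schema_rules()
  out <- data.frame(column = columns, type = NA_character_,
                    class = NA_character_, stringsAsFactors = FALSE)
  for (r in rules) {
    hit <- grepl(r[[1]], columns)
    out$type[hit & is.na(out$type)] <- r[[2]]
    out$class[hit & is.na(out$class)] <- r[[3]]
  }
  if (anyNA(out$type)) {
    config_error("no schema rule for column(s): %s",
                 paste(out$column[is.na(out$type)], collapse = ", "))
  }
  out
}

#' Assemble the baseline feature matrix for a cohort
#'
#' Joins the subject-level instruments (demographics, MoCA, SE-ADL,
#' Hoehn & Yahr, DaTScan SBRs when available), the baseline-visit
#' MDS-UPDRS subpart/Total scores (and optionally the individual item
#' responses), the polygenic scores and the monogenic flags into one
#' subjects-by-features data.frame with an attached [feature_schema()].
#'
#' @param cohort a `pd_cohort` (medication-adjusted values are used when
#'   the cohort has been adjusted).
#' @param prs_pd,prs_ea optional [compute_prs()] results (or named numeric
#'   vectors) added as `prs_pd` / `prs_ea`.
#' @param carriers optional carrier calls passed to [monogenic_flags()].
#' @param include_items include individual MDS-UPDRS item responses.
#' @param exclude_ess drop the Epworth Sleepiness Scale column (it adds
#'   minimal predictive value and is excluded from modelling by default).
#' @return data.frame (rownames = subject ids) with attribute `schema`.
#' @export
build_features <- function(cohort, prs_pd = NULL, prs_ea = NULL,
                           carriers = NULL, include_items = TRUE,
                           exclude_ess = TRUE) {
  stopifnot(inherits(cohort, "pd_cohort"))
  subj <- cohort$subjects
  base <- cohort$visits[cohort$visits$month == 0, ]
  keep_cols <- c("subject_id", "updrs1", "updrs2", "updrs3", "updrs_total")
  if (include_items) {
    keep_cols <- c(keep_cols, grep("^updrs\\d_", names(base), value = TRUE))
  }
  base <- base[, intersect(keep_cols, names(base))]
  X <- merge(subj, base, by = "subject_id", all.x = TRUE, sort = TRUE)
  as_vec <- function(x, nm) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "prs_result")) x <- x$score
    stopifnot(!is.null(names(x)))
    x[match(X$subject_id, names(x))]
  }
  if (!is.null(prs_pd)) X$prs_pd <- as_vec(prs_pd)
  if (!is.null(prs_ea)) X$prs_ea <- as_vec(prs_ea)
  if (!is.null(carriers)) {
    mf <- monogenic_flags(carriers)
    X <- merge(X, mf, by = "subject_id", all.x = TRUE, sort = TRUE)
  }
  rownames(X) <- X$subject_id
  drop <- c("subject_id", "treated_any", "treated_levodopa",
            "treated_agonist", "treated_other")
  if (exclude_ess) drop <- c(drop, "ess")
  X <- X[, setdiff(names(X), drop), drop = FALSE]
  attr(X, "schema") <- feature_schema(names(X))
  X
}

#' Drop features with more than a given missing fraction
#'
#' Columns whose missing fraction strictly exceeds the threshold are
#' removed (a column at exactly the threshold is retained).
#'
#' @param table data.frame of features.
#' @param threshold maximum tolerated missing fraction.
#' @return the filtered data.frame with attribute `dropped` naming the
#'   removed columns (with their missing fractions).
#' @export
drop_high_missingness <- function(table, threshold = 0.5) {
  frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  gone <- frac > threshold
  out <- table[, !gone, drop = FALSE]
  sch <- attr(table, "schema")
  if (!is.null(sch)) attr(out, "schema") <- sch[!gone, , drop = FALSE]
  attr(out, "dropped") <- frac[gone]
  out
}

#' Fit typed imputation values on training rows
#'
#' Continuous columns impute the training mean, ordinal columns the
#' training median, categorical columns the training mode.
#'
#' @param train training feature data.frame.
#' @param schema a [feature_schema()]; defaults to the one attached to
#'   `train`.
#' @return object of class `pd_imputer` (named list of imputation values).
#' @export
fit_imputer <- function(train, schema = attr(train, "schema")) {
  if (is.null(schema)) schema <- feature_schema(names(train))
  vals <- lapply(names(train), function(nm) {
    x <- train[[nm]]
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) {
      config_error("column '%s' is all-missing (drop it before imputing)", nm)
    }
    tp <- schema$type[schema$column == nm]
    switch(tp,
           continuous = mean(obs),
           ordinal = stats::median(obs),
           categorical = stat_mode(obs))
  })
  structure(stats::setNames(vals, names(train)), class = "pd_imputer")
}

#' Apply fitted imputation values
#'
#' @param table feature data.frame (training or any other cohort).
#' @param imputer a [fit_imputer()] result.
#' @return the table with no missing values in imputed columns.
#' @export
apply_imputer <- function(table, imputer) {
  stopifnot(inherits(imputer, "pd_imputer"))
  for (nm in intersect(names(table), names(imputer))) {
    x <- table[[nm]]
    x[is.na(x)] <- imputer[[nm]]
    table[[nm]] <- x
  }
  table
}

#' Fit a standard scaler on training rows
#'
#' Per-column mean and population standard deviation (divisor n, the
#' standard-scaler convention); transformed training columns have mean 0
#' and unit population variance. Zero-variance columns get scale 1 (with
#' a warning), i.e. they are centered but not rescaled.
#'
#' @param train complete (imputed) numeric training data.frame.
#' @return object of class `pd_scaler` with `center` and `scale` vectors.
#' @export
fit_scaler <- function(train) {
  m <- vapply(train, mean, numeric(1))
  s <- vapply(train, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  if (any(s == 0)) {
    warning(sprintf("zero-variance column(s) not rescaled: %s",
                    paste(names(s)[s == 0], collapse = ", ")))
    s[s == 0] <- 1
  }
  structure(list(center = m, scale = s), class = "pd_scaler")
}

#' Apply a fitted scaler
#'
#' @param table complete numeric data.frame.
#' @param scaler a [fit_scaler()] result.
#' @return standardized data.frame (training parameters, any rows).
#' @export
apply_scaler <- function(table, scaler) {
  stopifnot(inherits(scaler, "pd_scaler"))
  nm <- intersect(names(table), names(scaler$center))
  for (cl in nm) {
    table[[cl]] <- (table[[cl]] - scaler$center[[cl]]) / scaler$scale[[cl]]
  }
  table
}

# numeric matrix view of a feature data.frame (xgboost input)
feature_matrix <- function(table) {
  m <- as.matrix(as.data.frame(lapply(table, as.numeric)))
  rownames(m) <- rownames(table)
  m
}

#' Fit the Shapley explainer model
#'
#' A gradient-boosted tree classifier with fixed moderate settings whose
#' exact tree-path attributions drive feature ranking and selection.
#'
#' @param X numeric feature matrix (or data.frame).
#' @param y 0/1 labels.
#' @param nrounds boosting rounds.
#' @param seed integer seed.
#' @return an `xgb.Booster`.
#' @export
fit_explainer <- function(X, y, nrounds = 120, seed = 1) {
  X <- feature_matrix(as.data.frame(X))
  set.seed(seed)
  d <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.1, max_depth = 5,
                  subsample = 0.9, colsample_bytree = 0.9,
                  nthread = 1, seed = seed),
    data = d, nrounds = nrounds, verbose = 0)
}

#' Per-row Shapley attributions of a tree model
#'
#' Exact tree-path attributions (`predcontrib`): one column per feature
#' plus the base value; rows sum to the model margin.
#'
#' @param model an `xgb.Booster`.
#' @param X the feature matrix the model consumes.
#' @return list with `contrib` (rows x features) and `base` (base values).
#' @export
shap_values <- function(model, X) {
  X <- feature_matrix(as.data.frame(X))
  ct <- stats::predict(model, X, predcontrib = TRUE)
  colnames(ct) <- c(colnames(X), "BIAS")
  list(contrib = ct[, colnames(X), drop = FALSE], base = ct[, "BIAS"])
}

#' Rank features by mean absolute Shapley attribution
#'
#' @param model fitted classifier (an `xgb.Booster`).
#' @param X feature matrix/data.frame the model was trained on.
#' @return data.frame ordered by decreasing importance: `feature`,
#'   `mean_abs_shap`, `mean_shap`, `direction` (correlation between the
#'   feature value and its attribution: negative means high values push
#'   towards non-progression). Ties are broken alphabetically.
#' @export
rank_features <- function(model, X) {
  Xm <- feature_matrix(as.data.frame(X))
  sv <- shap_values(model, Xm)$contrib
  imp <- colMeans(abs(sv))
  dir <- vapply(seq_len(ncol(Xm)), function(j) {
    if (stats::sd(Xm[, j]) == 0 || stats::sd(sv[, j]) == 0) return(0)
    stats::cor(Xm[, j], sv[, j])
  }, numeric(1))
  out <- data.frame(feature = colnames(Xm), mean_abs_shap = imp,
                    mean_shap = colMeans(sv), direction = dir,
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_shap, out$feature), , drop = FALSE]
}

#' Select the top-k ranked features
#'
#' @param ranking a [rank_features()] result.
#' @param k number of features to keep (all, with a warning, if fewer are
#'   available).
#' @return character vector of feature names.
#' @export
select_top <- function(ranking, k = 25) {
  if (nrow(ranking) < k) {
    warning(sprintf("only %d features available (k = %d): keeping all",
                    nrow(ranking), k))
    k <- nrow(ranking)
  }
  ranking$feature[seq_len(k)]
}
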
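# Classification metrics with uncertainty, group comparisons and polygenic
# score distribution contrasts.

#' Confusion matrix and derived classification metrics
#'
#' Computes the confusion matrix at a fixed probability threshold together
#' with F1, sensitivity, specificity, PPV, NPV, ROC AUC (trapezoidal rule
#' over all thresholds) and PR AUC (step interpolation, see Details).
#'
#' @details
#' The ROC AUC is the area under the empirical ROC curve computed by the
#' trapezoidal rule, which is identical to the normalized Mann-Whitney U
#' statistic (ties counted half). The PR AUC uses the conservative step
#' convention: precision is held constant between successive recall points
#' (no linear interpolation), i.e. \eqn{\sum_k (R_k - R_{k-1}) P_k} over
#' distinct score thresholds in decreasing order.
#'
#' If `y_true` contains a single class, ROC and PR AUC are undefined and
#' reported as `NA` with a warning.
#'
#' @param y_true 0/1 (or logical) vector of true labels.
#' @param y_prob numeric vector of predicted probabilities in \[0, 1\].
#' @param threshold classification threshold for the confusion matrix.
#' @return a list of class `eval_entry` with elements `f1`, `roc_auc`,
#'   `pr_auc`, `confusion` (tp, fp, fn, tn), `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy`, `n`, `prevalence`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.3, 0.1))
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y <- as.integer(as.logical(y_true))
  stopifnot(length(y) == length(y_prob))
  if (anyNA(y) || anyNA(y_prob)) config_error("labels and scores must be complete")
  if (any(y_prob < 0 | y_prob > 1)) config_error("y_prob must lie in [0, 1]")
  pred <- as.integer(y_prob > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  if (length(unique(y)) < 2L) {
    warning("single-class labels: ROC/PR AUC undefined, reported as NA")
    roc <- NA_real_; pr <- NA_real_
  } else {
    roc <- roc_auc(y, y_prob)
    pr <- pr_auc(y, y_prob)
  }
  structure(list(
    f1 = f1, roc_auc = roc, pr_auc = pr,
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    sensitivity = recall,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = precision,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / length(y),
    n = length(y), prevalence = mean(y)
  ), class = "eval_entry")
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @param y_true 0/1 labels with both classes present.
#' @param y_prob numeric scores.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, y_prob) {
  y <- as.integer(as.logical(y_true))
  ord <- order(y_prob, decreasing = TRUE)
  y <- y[ord]; p <- y_prob[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  stopifnot(n_pos > 0, n_neg > 0)
  # cumulative TP/FP at each distinct threshold
  dup <- rev(duplicated(rev(p)))  # TRUE if the next score is identical
  tp <- cumsum(y == 1)[!dup]
  fp <- cumsum(y == 0)[!dup]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Precision is treated as a step function of recall between successive
#' distinct thresholds; no linear interpolation is applied between PR
#' points.
#'
#' @inheritParams roc_auc
#' @return scalar PR AUC in \[0, 1\].
#' @export
pr_auc <- function(y_true, y_prob) {
  y <- as.integer(as.logical(y_true))
  ord <- order(y_prob, decreasing = TRUE)
  y <- y[ord]; p <- y_prob[ord]
  n_pos <- sum(y == 1)
  stopifnot(n_pos > 0, sum(y == 0) > 0)
  dup <- rev(duplicated(rev(p)))
  tp <- cumsum(y == 1)[!dup]
  k <- seq_along(y)[!dup]
  precision <- tp / k
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Bootstrap interval half-width for a classification metric
#'
#' Subject-level nonparametric bootstrap: resamples (label, score) pairs
#' with replacement and reports the percentile interval half-width of the
#' metric. Resamples that degenerate to a single class (where the metric is
#' undefined) are skipped and counted.
#'
#' @param metric_fn function of `(y_true, y_prob)` returning a scalar.
#' @param y_true,y_prob as in [classification_metrics()].
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `half_width`, `lower`, `upper`, `point`,
#'   `n_degenerate`.
#' @export
bootstrap_ci <- function(metric_fn, y_true, y_prob, B = 1000, level = 0.95,
                         seed = 1) {
  stopifnot(B >= 100)
  y <- as.integer(as.logical(y_true))
  n <- length(y)
  set.seed(seed)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2L) next
    vals[b] <- metric_fn(y[idx], y_prob[idx])
  }
  n_deg <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(half_width = (qs[2] - qs[1]) / 2, lower = qs[1], upper = qs[2],
       point = metric_fn(y, y_prob), n_degenerate = n_deg)
}

#' Compare baseline features between progressors and non-progressors
#'
#' For every numeric feature, reports group means with standard errors and
#' the two-sided Wilcoxon rank-sum p-value (exact for small tie-free
#' samples, normal approximation with continuity correction otherwise, as
#' implemented by [stats::wilcox.test()]).
#'
#' @param features data.frame of numeric features (rows = subjects).
#' @param group logical/0-1 vector: `TRUE` = progressor.
#' @return data.frame with one row per feature: group means, SEs, and
#'   `p_value`. All-tied features get `p_value = 1` with a warning.
#' @export
group_compare <- function(features, group) {
  g <- as.logical(group)
  stopifnot(nrow(features) == length(g))
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  res <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    x1 <- x[g & !is.na(x)]; x0 <- x[!g & !is.na(x)]
    se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    p <- if (length(unique(c(x1, x0))) < 2L) {
      warning(sprintf("feature '%s' is constant: p set to 1", nm))
      1
    } else {
      suppressWarnings(stats::wilcox.test(x1, x0)$p.value)
    }
    data.frame(feature = nm,
               mean_progressor = mean(x1), se_progressor = se(x1),
               mean_nonprogressor = mean(x0), se_nonprogressor = se(x0),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Polygenic-score distribution contrasts by progression status
#'
#' For each progression target, compares the polygenic score distribution of
#' progressors vs non-progressors: group medians, direction of the shift,
#' and the two-sided Wilcoxon rank-sum p-value.
#'
#' @param scores named numeric vector (or 1-column data.frame) of per-subject
#'   polygenic scores; names are subject ids.
#' @param labels a `progression_labels` data.frame (see
#'   [label_progression()]) or any data.frame with columns `subject_id`,
#'   `part`, `horizon`, `progressor`.
#' @param score_name label used in the output.
#' @return data.frame with one row per (part, horizon): medians by status,
#'   `shift` ("progressors_higher"/"progressors_lower"/"none"), `p_value`,
#'   `n_matched`, `n_dropped`.
#' @export
prs_distribution_report <- function(scores, labels, score_name = "prs") {
  if (is.data.frame(scores)) scores <- stats::setNames(scores[[2]], scores[[1]])
  stopifnot(!is.null(names(scores)))
  targets <- unique(labels[, c("part", "horizon")])
  out <- lapply(seq_len(nrow(targets)), function(i) {
    sub <- labels[labels$part == targets$part[i] &
                    labels$horizon == targets$horizon[i] &
                    !is.na(labels$progressor), ]
    s <- scores[match(sub$subject_id, names(scores))]
    keep <- !is.na(s)
    n_drop <- sum(!keep)
    s <- s[keep]; pg <- sub$progressor[keep]
    if (length(unique(pg)) < 2L) {
      config_error("target %s/%s has a single progression class",
                   targets$part[i], targets$horizon[i])
    }
    m1 <- stats::median(s[pg]); m0 <- stats::median(s[!pg])
    p <- suppressWarnings(stats::wilcox.test(s[pg], s[!pg])$p.value)
    data.frame(score = score_name, part = targets$part[i],
               horizon = targets$horizon[i],
               median_progressor = m1, median_nonprogressor = m0,
               shift = if (m1 > m0) "progressors_higher"
                       else if (m1 < m0) "progressors_lower" else "none",
               p_value = p, n_matched = length(s), n_dropped = n_drop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.eval_entry <- function(x, ...) {
  cat(sprintf(
    "classification metrics (n = %d, prevalence = %.2f)\n", x$n, x$prevalence))
  cat(sprintf("  F1 = %.3f  ROC AUC = %.3f  PR AUC = %.3f\n",
              x$f1, x$roc_auc, x$pr_auc))
  cm <- x$confusion
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
              cm["tp"], cm["fp"], cm["fn"], cm["tn"]))
  invisible(x)
}
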
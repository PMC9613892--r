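# Medication adjustment, progressor labelling, annualized trajectories and
# label-overlap analysis.
#
# MDS-UPDRS scores of treated subjects are masked downward by symptomatic
# medication. Labels are therefore computed on medication-adjusted scores:
# a constant per-subpart offset, equal to the training-cohort mean
# untreated-minus-treated difference pooled over all visits, is added to
# every treated subject's scores. Because the offset is constant across
# timepoints it cancels in any two-endpoint slope, so the labels themselves
# are invariant to the adjustment; the adjustment matters for any analysis
# of score levels.

PARTS <- c("I", "II", "III")
PART_COLS <- c(I = "updrs1", II = "updrs2", III = "updrs3")

#' Estimate medication-adjustment offsets from a training cohort
#'
#' For each MDS-UPDRS subpart, the offset is the mean score of untreated
#' subjects minus the mean score of treated subjects, pooled across all
#' visits. "Treated" means treated at any point during follow-up
#' (`treated_any` flag). Offsets are estimated on the training cohort only
#' and reapplied unchanged elsewhere.
#'
#' @param train a `pd_cohort` (see [generate_cohort()] or [pd_cohort()]).
#' @return object of class `adjustment_offsets`: named numeric vector
#'   (I, II, III).
#' @export
estimate_offsets <- function(train) {
  stopifnot(inherits(train, "pd_cohort"))
  treated <- train$subjects$subject_id[train$subjects$treated_any == 1]
  untreated <- setdiff(train$subjects$subject_id, treated)
  if (length(treated) == 0L || length(untreated) == 0L) {
    config_error("offset estimation needs both treated and untreated subjects")
  }
  vis <- train$visits
  is_tr <- vis$subject_id %in% treated
  off <- vapply(PART_COLS, function(cl) {
    mean(vis[[cl]][!is_tr], na.rm = TRUE) - mean(vis[[cl]][is_tr], na.rm = TRUE)
  }, numeric(1))
  names(off) <- PARTS
  structure(off, class = "adjustment_offsets")
}

#' @export
print.adjustment_offsets <- function(x, ...) {
  cat(sprintf("medication-adjustment offsets: I %+.3f, II %+.3f, III %+.3f\n",
              x[["I"]], x[["II"]], x[["III"]]))
  invisible(x)
}

#' Apply medication-adjustment offsets to a cohort
#'
#' Adds the per-subpart offset to every visit score of treated subjects
#' (untreated subjects are unchanged) and recomputes the Total as the sum
#' of the adjusted subparts.
#'
#' @param cohort a `pd_cohort`.
#' @param off an [estimate_offsets()] result, or a named numeric vector
#'   with entries I, II, III.
#' @return the adjusted `pd_cohort`.
#' @export
apply_adjustment <- function(cohort, off) {
  stopifnot(inherits(cohort, "pd_cohort"))
  off <- unclass(off)[PARTS]
  stopifnot(all(is.finite(off)))
  treated <- cohort$subjects$subject_id[cohort$subjects$treated_any == 1]
  vis <- cohort$visits
  is_tr <- vis$subject_id %in% treated
  for (p in PARTS) vis[[PART_COLS[p]]][is_tr] <- vis[[PART_COLS[p]]][is_tr] + off[[p]]
  vis$updrs_total <- vis$updrs1 + vis$updrs2 + vis$updrs3
  cohort$visits <- vis
  cohort$adjusted <- TRUE
  cohort
}

# value of `col` at the visit nearest `month` within +/- window, NA if none
value_at <- function(vis_sub, col, month, window = 3) {
  d <- abs(vis_sub$month - month)
  ok <- which(d <= window)
  if (length(ok) == 0L) return(NA_real_)
  vis_sub[[col]][ok[which.min(d[ok])]]
}

#' Progressor / non-progressor labels for all subpart x horizon targets
#'
#' For each subject and each target (MDS-UPDRS I, II, III and Total at 12,
#' 24 and 36 months) the annualized two-endpoint slope is
#' `(value at horizon - value at baseline) / (horizon / 12)`, using the
#' visit nearest the nominal month within a +/- 3 month window. A subject is
#' a progressor iff the slope is strictly positive; a slope of zero or
#' below is a non-progressor. Subjects missing an endpoint are excluded
#' from that target only (label NA).
#'
#' @param cohort a `pd_cohort` (adjusted or not: constant offsets cancel in
#'   the slope, so labels are identical either way).
#' @param horizons months post baseline.
#' @param window endpoint-matching half-window in months.
#' @return data.frame of class `progression_labels` with columns
#'   `subject_id`, `part` ("I", "II", "III", "Total"), `horizon`, `slope`
#'   (points/year), `progressor` (logical, NA if unlabelable).
#' @export
label_progression <- function(cohort, horizons = c(12, 24, 36), window = 3) {
  stopifnot(inherits(cohort, "pd_cohort"))
  cols <- c(PART_COLS, Total = "updrs_total")
  vis_by_subj <- split(cohort$visits, cohort$visits$subject_id)
  ids <- cohort$subjects$subject_id
  grid <- expand.grid(part = names(cols), horizon = horizons,
                      stringsAsFactors = FALSE)
  out <- lapply(ids, function(id) {
    vs <- vis_by_subj[[as.character(id)]]
    res <- grid
    res$subject_id <- id
    res$slope <- NA_real_
    for (k in seq_len(nrow(grid))) {
      if (is.null(vs)) break
      v0 <- value_at(vs, cols[[grid$part[k]]], 0, window)
      vh <- value_at(vs, cols[[grid$part[k]]], grid$horizon[k], window)
      if (!is.na(v0) && !is.na(vh)) {
        res$slope[k] <- (vh - v0) / (grid$horizon[k] / 12)
      }
    }
    res
  })
  out <- do.call(rbind, out)
  out$progressor <- ifelse(is.na(out$slope), NA, out$slope > 0)
  out <- out[, c("subject_id", "part", "horizon", "slope", "progressor")]
  n_missing <- sum(is.na(out$progressor))
  if (n_missing > 0) {
    message(sprintf("%d of %d subject-targets unlabelable (missing endpoint visit)",
                    n_missing, nrow(out)))
  }
  class(out) <- c("progression_labels", "data.frame")
  out
}

#' Extract one label target as a named logical vector
#'
#' @param labels a [label_progression()] result.
#' @param part one of "I", "II", "III", "Total".
#' @param horizon months.
#' @param drop_na drop unlabelable subjects.
#' @return named logical vector (names = subject ids).
#' @export
label_vector <- function(labels, part, horizon, drop_na = TRUE) {
  sub <- labels[labels$part == part & labels$horizon == horizon, ]
  v <- stats::setNames(sub$progressor, sub$subject_id)
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Annualized 12-month-lag trajectory series
#'
#' At each visit month m >= 12 with a visit 12 months earlier, the lag
#' slope is `value(m) - value(m - 12)` (points/year, since the lag is one
#' year). Points with a missing lagged visit are omitted.
#'
#' @param cohort a `pd_cohort`.
#' @param part "I", "II", "III" or "Total".
#' @param window visit-matching half-window in months.
#' @return data.frame `subject_id`, `month`, `lag_slope`.
#' @export
annualized_trajectory <- function(cohort, part = "Total", window = 3) {
  stopifnot(inherits(cohort, "pd_cohort"))
  col <- c(PART_COLS, Total = "updrs_total")[[part]]
  out <- lapply(split(cohort$visits, cohort$visits$subject_id), function(vs) {
    months <- sort(vs$month[vs$month >= 12])
    if (length(months) == 0L) return(NULL)
    sl <- vapply(months, function(m) {
      v1 <- value_at(vs, col, m, window = 0)
      v0 <- value_at(vs, col, m - 12, window = window)
      if (is.na(v0) || is.na(v1)) NA_real_ else v1 - v0
    }, numeric(1))
    keep <- !is.na(sl)
    if (!any(keep)) return(NULL)
    data.frame(subject_id = vs$subject_id[1], month = months[keep],
               lag_slope = sl[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean lag-slope trajectories by 12-month Total progression status
#'
#' @param traj an [annualized_trajectory()] result.
#' @param labels a [label_progression()] result (the 12-month Total target
#'   defines the grouping).
#' @return data.frame `month`, `status`, `mean_lag_slope`, `n`.
#' @export
trajectory_by_status <- function(traj, labels) {
  lv <- label_vector(labels, "Total", 12)
  traj$status <- ifelse(lv[as.character(traj$subject_id)],
                        "progressor", "non-progressor")
  traj <- traj[!is.na(traj$status), ]
  agg <- stats::aggregate(lag_slope ~ month + status, data = traj,
                          FUN = mean)
  cnt <- stats::aggregate(lag_slope ~ month + status, data = traj,
                          FUN = length)
  names(agg)[3] <- "mean_lag_slope"
  agg$n <- cnt$lag_slope
  agg
}

#' Jaccard overlap of progressor sets across targets
#'
#' For a fixed horizon, computes the 4 x 4 matrix of Jaccard similarities
#' `J(A, B) = |A intersect B| / |A union B|` between the progressor sets of
#' MDS-UPDRS I, II, III and Total, over subjects labelable for both targets
#' of each pair. If both sets are empty, J is defined as 1 with a warning.
#'
#' @param labels a [label_progression()] result.
#' @param horizon months.
#' @return symmetric 4 x 4 numeric matrix with unit diagonal.
#' @export
jaccard_overlap <- function(labels, horizon = 12) {
  parts <- c(PARTS, "Total")
  vecs <- lapply(parts, function(p) label_vector(labels, p, horizon))
  names(vecs) <- parts
  m <- matrix(NA_real_, 4, 4, dimnames = list(parts, parts))
  for (a in seq_along(parts)) {
    for (b in seq_len(a)) {
      va <- vecs[[a]]; vb <- vecs[[b]]
      common <- intersect(names(va), names(vb))
      A <- names(va)[va][names(va)[va] %in% common]
      B <- names(vb)[vb][names(vb)[vb] %in% common]
      u <- length(union(A, B))
      if (u == 0L) {
        warning(sprintf("both progressor sets empty for %s vs %s: J set to 1",
                        parts[a], parts[b]))
        j <- 1
      } else {
        j <- length(intersect(A, B)) / u
      }
      m[a, b] <- j; m[b, a] <- j
    }
  }
  m
}
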
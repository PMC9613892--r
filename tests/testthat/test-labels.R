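# Medication adjustment, progressor labelling, trajectories and overlap.

make_two_visit_cohort <- function(values) {
  # values: data.frame subject_id, treated, u1_0, u2_0, u3_0, u1_12, ...
  subjects <- data.frame(subject_id = values$subject_id,
                         treated_any = values$treated,
                         stringsAsFactors = FALSE)
  visits <- rbind(
    data.frame(subject_id = values$subject_id, month = 0,
               updrs1 = values$u1_0, updrs2 = values$u2_0,
               updrs3 = values$u3_0),
    data.frame(subject_id = values$subject_id, month = 12,
               updrs1 = values$u1_12, updrs2 = values$u2_12,
               updrs3 = values$u3_12))
  visits$updrs_total <- visits$updrs1 + visits$updrs2 + visits$updrs3
  pd_cohort(subjects, visits)
}

test_that("offsets recover a planted masking difference and error without both groups", {
  sim <- cached_sim("ppmi_like", n = 2000, seed = 104)
  off <- estimate_offsets(sim$cohort)
  # the generator masks treated scores by -0.67, -1.5, -3.67; the
  # estimator's sampling error is dominated by between-subject
  # heterogeneity (SE ~ 0.2 score points at this size)
  expect_equal(off[["I"]], 0.67, tolerance = 0.9)
  expect_equal(off[["II"]], 1.5, tolerance = 0.6)
  expect_equal(off[["III"]], 3.67, tolerance = 0.6)
  expect_gt(off[["I"]], 0); expect_gt(off[["II"]], 0); expect_gt(off[["III"]], 0)
  # treated and untreated identical -> offsets near zero
  co <- make_two_visit_cohort(data.frame(
    subject_id = sprintf("s%d", 1:8), treated = rep(c(0, 1), 4),
    u1_0 = 4, u2_0 = 4, u3_0 = 20, u1_12 = 5, u2_12 = 5, u3_12 = 21))
  off0 <- estimate_offsets(co)
  expect_equal(unclass(off0), c(I = 0, II = 0, III = 0), tolerance = 1e-12)
  co_all <- co
  co_all$subjects$treated_any <- 1
  expect_error(estimate_offsets(co_all), "both treated and untreated")
})

test_that("adjustment shifts treated subjects only and recomputes the Total", {
  co <- make_two_visit_cohort(data.frame(
    subject_id = c("t", "u"), treated = c(1, 0),
    u1_0 = 4, u2_0 = 3, u3_0 = 20, u1_12 = 4, u2_12 = 3, u3_12 = 20))
  adj <- apply_adjustment(co, c(I = 0.67, II = 1.5, III = 3.67))
  vt <- adj$visits[adj$visits$subject_id == "t" & adj$visits$month == 0, ]
  vu <- adj$visits[adj$visits$subject_id == "u" & adj$visits$month == 0, ]
  expect_equal(vt$updrs3, 23.67)
  expect_equal(vt$updrs_total, 4.67 + 4.5 + 23.67)
  expect_equal(vu$updrs3, 20)   # untreated unchanged
  expect_equal(vu$updrs_total, 27)
})

test_that("labels are invariant to any constant medication adjustment", {
  sim <- cached_sim("ppmi_like", n = 200, seed = 103)
  lab0 <- suppressMessages(label_progression(sim$cohort))
  set.seed(9)
  for (i in 1:5) {
    off <- c(I = runif(1, -3, 3), II = runif(1, -3, 3), III = runif(1, -5, 5))
    lab1 <- suppressMessages(label_progression(apply_adjustment(sim$cohort, off)))
    expect_identical(lab1$progressor, lab0$progressor)
  }
})

test_that("slopes are annualized two-endpoint differences; labels per target", {
  co <- make_two_visit_cohort(data.frame(
    subject_id = c("p", "z", "mix"), treated = 0,
    u1_0 = c(4, 4, 4), u2_0 = c(3, 3, 6), u3_0 = c(16.6, 20, 20),
    u1_12 = c(5, 4, 6), u2_12 = c(4, 3, 4), u3_12 = c(16, 20, 17)))
  lab <- suppressMessages(label_progression(co, horizons = 12))
  lv <- function(part) label_vector(lab, part, 12)
  # "p": Total 23.6 -> 25, progressor
  expect_true(lv("Total")[["p"]])
  expect_equal(lab$slope[lab$subject_id == "p" & lab$part == "Total"], 1.4)
  # "z": unchanged (slope 0) -> non-progressor
  expect_false(lv("Total")[["z"]])
  # "mix": I rises, II and III fall enough that Total falls
  expect_true(lv("I")[["mix"]])
  expect_false(lv("Total")[["mix"]])
  # Total slope identity: sum of subpart slopes
  for (s in c("p", "z", "mix")) {
    parts <- sapply(c("I", "II", "III"), function(pp)
      lab$slope[lab$subject_id == s & lab$part == pp])
    expect_equal(sum(parts),
                 lab$slope[lab$subject_id == s & lab$part == "Total"],
                 tolerance = 1e-12)
  }
})

test_that("Total slope equals the sum of subpart slopes at every horizon (simulated)", {
  sim <- cached_sim("ppmi_like", n = 200, seed = 103)
  lab <- suppressMessages(label_progression(sim$cohort))
  for (h in c(12, 24, 36)) {
    sub <- lab[lab$horizon == h, ]
    wide <- reshape(sub[, c("subject_id", "part", "slope")],
                    idvar = "subject_id", timevar = "part",
                    direction = "wide")
    ok <- complete.cases(wide)
    expect_equal(wide$slope.Total[ok],
                 wide$slope.I[ok] + wide$slope.II[ok] + wide$slope.III[ok],
                 tolerance = 1e-9)
  }
})

test_that("monotone relabeling: raising a horizon value never unmakes a progressor", {
  sim <- cached_sim("ppmi_like", n = 200, seed = 103)
  co <- sim$cohort
  lab0 <- suppressMessages(label_progression(co, horizons = 12))
  co2 <- co
  at12 <- co2$visits$month == 12
  co2$visits$updrs3[at12] <- co2$visits$updrs3[at12] + 5
  co2$visits$updrs_total <- co2$visits$updrs1 + co2$visits$updrs2 +
    co2$visits$updrs3
  lab1 <- suppressMessages(label_progression(co2, horizons = 12))
  for (part in c("III", "Total")) {
    v0 <- label_vector(lab0, part, 12)
    v1 <- label_vector(lab1, part, 12)[names(v0)]
    expect_true(all(v1[v0]))   # progressors stay progressors
  }
})

test_that("missing endpoints drop a subject from that target only", {
  sim <- cached_sim("ppmi_like", n = 200, seed = 103)
  co <- sim$cohort
  drop_id <- co$subjects$subject_id[1]
  co$visits <- co$visits[!(co$visits$subject_id == drop_id &
                             co$visits$month == 36), ]
  lab <- suppressMessages(label_progression(co))
  expect_true(all(is.na(lab$progressor[lab$subject_id == drop_id &
                                         lab$horizon == 36])))
  expect_false(anyNA(lab$progressor[lab$subject_id == drop_id &
                                      lab$horizon == 12]))
})

test_that("annualized lag-slope series: constants, linear ramps and mean reversion", {
  subjects <- data.frame(subject_id = c("const", "lin"), treated_any = 0)
  months <- c(0, 6, 12, 18, 24, 30, 36)
  visits <- do.call(rbind, lapply(months, function(m) {
    data.frame(subject_id = c("const", "lin"), month = m,
               updrs1 = c(4, 4), updrs2 = c(4, 4),
               updrs3 = c(20, 20 + 3 * m / 12))
  }))
  visits$updrs_total <- visits$updrs1 + visits$updrs2 + visits$updrs3
  co <- pd_cohort(subjects, visits)
  tr <- annualized_trajectory(co, "III")
  expect_equal(tr$lag_slope[tr$subject_id == "const"], rep(0, 5))
  expect_equal(tr$lag_slope[tr$subject_id == "lin"], rep(3, 5))
  # generator's planted mean reversion: initial progressors slow down
  sim <- cached_sim("ppmi_like", n = 1000, seed = 102)
  lab <- suppressMessages(label_progression(sim$cohort))
  traj <- annualized_trajectory(sim$cohort, "Total")
  by_status <- trajectory_by_status(traj, lab)
  prog <- by_status[by_status$status == "progressor", ]
  expect_gt(prog$mean_lag_slope[prog$month == 12],
            prog$mean_lag_slope[prog$month == 24])
})

test_that("Jaccard overlap matches set arithmetic and is a proper similarity", {
  lab <- data.frame(
    subject_id = rep(letters[1:4], times = 2),
    part = rep(c("I", "II"), each = 4),
    horizon = 12,
    slope = c(1, 1, 1, -1, -1, 1, 1, 1),
    progressor = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  lab <- rbind(lab,
               data.frame(subject_id = letters[1:4], part = "III", horizon = 12,
                          slope = c(1, 1, 1, -1),
                          progressor = c(TRUE, TRUE, TRUE, FALSE)),
               data.frame(subject_id = letters[1:4], part = "Total", horizon = 12,
                          slope = -1, progressor = FALSE))
  class(lab) <- c("progression_labels", "data.frame")
  J <- suppressWarnings(jaccard_overlap(lab, 12))
  # progressor sets {a,b,c} vs {b,c,d}: J = 2/4
  expect_equal(J["I", "II"], 0.5)
  # identical sets
  expect_equal(J["I", "III"], 1)
  expect_true(isSymmetric(J))
  expect_equal(unname(diag(J)), rep(1, 4))
  expect_true(all(J >= 0 & J <= 1))
  # progressor set disjoint from the empty Total set -> 0
  expect_equal(J["I", "Total"], 0)
  # both sets empty (Total vs Total) -> defined as 1 with a warning
  expect_warning(jaccard_overlap(lab, 12), "empty")
})
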
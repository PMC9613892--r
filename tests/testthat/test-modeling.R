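# Stratified splitting, randomized search, comparators and the stacked fit.

test_that("stratified splits preserve prevalence and are deterministic", {
  y <- setNames(rep(c(TRUE, FALSE), c(64, 36)), sprintf("s%03d", 1:100))
  sp <- stratified_split(y, 0.75, seed = 1)
  expect_setequal(c(sp$train, sp$test), names(y))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(sum(y[sp$train]), 48)   # 64 * 0.75
  expect_identical(sp, stratified_split(y, 0.75, seed = 1))
  expect_false(identical(sp, stratified_split(y, 0.75, seed = 2)))
  expect_error(stratified_split(setNames(c(TRUE, FALSE, FALSE), letters[1:3])),
               "at least 2")
  # Monte-Carlo contract: prevalence difference stays within 0.03
  set.seed(5)
  for (i in 1:100) {
    n <- sample(100:400, 1)
    yy <- setNames(rbinom(n, 1, runif(1, 0.3, 0.7)) == 1,
                   sprintf("x%04d", 1:n))
    if (min(table(yy)) < 2) next
    spp <- stratified_split(yy, 0.75, seed = i)
    expect_lt(abs(mean(yy[spp$train]) - mean(yy)), 0.03)
  }
})

test_that("sampled hyperparameters respect the search-space ranges", {
  draws <- sample_params(200, seed = 3)
  for (d in draws) {
    for (nm in c("lambda", "alpha", "eta", "gamma", "rate_drop", "skip_drop")) {
      expect_gte(d[[nm]], 1e-8); expect_lte(d[[nm]], 1)
    }
    expect_gte(d$subsample, 0.5); expect_lte(d$subsample, 1)
    expect_gte(d$colsample_bytree, 0.5); expect_lte(d$colsample_bytree, 1)
    expect_gte(d$scale_pos_weight, 0.8); expect_lte(d$scale_pos_weight, 1.2)
    expect_true(d$max_depth %in% 6:36)
    expect_gte(d$min_child_weight, 1); expect_lte(d$min_child_weight, 10)
    expect_true(d$grow_policy %in% c("depthwise", "lossguide"))
    expect_true(d$sample_type %in% c("uniform", "weighted"))
    expect_true(d$normalize_type %in% c("tree", "forest"))
  }
  # log-uniform draws cover several decades
  etas <- sapply(draws, `[[`, "eta")
  expect_gt(diff(range(log10(etas))), 4)
  expect_error(sample_params(0), "n_trials")
})

test_that("a single-trial search returns that draw; tuning beats the default on separable data", {
  set.seed(7)
  X <- matrix(rnorm(160 * 6), 160, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.numeric(plogis(3 * X[, 1]) > runif(160))
  names(y) <- rownames(X) <- sprintf("r%03d", 1:160)
  t1 <- tune_submodel(X[1:120, ], y[1:120], X[121:160, ], y[121:160],
                      n_trials = 1, seed = 9, nrounds = 40)
  expect_identical(t1$params, sample_params(1, seed = 9)[[1]])
  expect_equal(t1$trial, 1L)
  # paired comparison against an untuned default configuration
  wins <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    Xs <- matrix(rnorm(200 * 6), 200, 6)
    ys <- as.numeric(plogis(3 * Xs[, 1]) > runif(200))
    tr <- 1:150; va <- 151:200
    tuned <- tune_submodel(Xs[tr, ], ys[tr], Xs[va, ], ys[va],
                           n_trials = 6, seed = s, nrounds = 60)
    m0 <- fit_explainer(Xs[tr, ], ys[tr], nrounds = 60, seed = s)
    f1_default <- pdstack:::f1_at(ys[va], predict(m0, Xs[va, ]))
    if (tuned$val_f1 >= f1_default) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("a leaked label column is refused", {
  y <- setNames(rep(c(TRUE, FALSE), each = 30), sprintf("r%03d", 1:60))
  X <- data.frame(good = rnorm(60), leak = as.numeric(y))
  rownames(X) <- names(y)
  expect_error(
    pdstack:::train_one_target(X, y, top_k = 2, n_trials = 1, n_folds = 2,
                               nrounds = 10, seed = 1),
    "leaked")
})

test_that("comparators: logistic regression separates, balanced forest helps the minority", {
  set.seed(17)
  X <- data.frame(x1 = c(rnorm(60, -2), rnorm(60, 2)), x2 = rnorm(120))
  y <- rep(c(0, 1), each = 60)
  cmp <- comparator_models(X[1:90, ], y[1:90], X[91:120, ], y[91:120],
                           seed = 1)
  expect_gte(cmp$lr$f1, 0.95)
  cmp2 <- comparator_models(X[1:90, ], y[1:90], X[91:120, ], y[91:120],
                            seed = 1)
  expect_identical(cmp$lr$f1, cmp2$lr$f1)
  expect_identical(cmp$brf$f1, cmp2$brf$f1)
  # 80:20 imbalance: balanced sampling recalls the minority at least as
  # well as an unweighted forest in most seeds
  wins <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 300
    yy <- rbinom(n, 1, 0.2)
    XX <- data.frame(x1 = rnorm(n, 1.2 * yy), x2 = rnorm(n, -0.8 * yy))
    tr <- 1:200; te <- 201:300
    if (sum(yy[tr] == 1) < 5 || sum(yy[te] == 1) < 3) { wins <- wins + 1; next }
    yf <- factor(yy[tr], levels = c(0, 1))
    nmin <- min(table(yf))
    set.seed(s)
    bal <- randomForest::randomForest(XX[tr, ], yf, ntree = 150,
                                      strata = yf, sampsize = c(nmin, nmin))
    set.seed(s)
    unw <- randomForest::randomForest(XX[tr, ], yf, ntree = 150)
    rec <- function(m) {
      pred <- predict(m, XX[te, ])
      sum(pred == "1" & yy[te] == 1) / sum(yy[te] == 1)
    }
    if (rec(bal) >= rec(unw)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("oracle meta-features are perfectly recoverable; shuffling destroys them", {
  set.seed(23)
  n <- 240
  y <- setNames(rbinom(n, 1, 0.5) == 1, sprintf("m%03d", 1:n))
  X <- data.frame(p_oracle = ifelse(y, runif(n, 0.8, 1), runif(n, 0, 0.2)),
                  noise = rnorm(n))
  rownames(X) <- names(y)
  fit <- pdstack:::train_one_target(X, y, top_k = 2, n_trials = 2,
                                    n_folds = 3, nrounds = 30, seed = 3,
                                    objective = "auc", cv_tune = TRUE)
  prob <- predict(fit$model, pdstack:::feature_matrix(X[, fit$features,
                                                        drop = FALSE]))
  expect_equal(pdstack:::f1_at(as.numeric(y), prob), 1)
  # row-shuffled meta-features carry no signal
  Xs <- X[sample(n), , drop = FALSE]
  rownames(Xs) <- names(y)
  fit2 <- pdstack:::train_one_target(Xs, y, top_k = 2, n_trials = 2,
                                     n_folds = 3, nrounds = 30, seed = 4)
  ok <- !is.na(fit2$oof)
  expect_lt(abs(roc_auc(y[ok], fit2$oof[ok]) - 0.5), 0.12)
})

test_that("the stacked fit trains all models, predicts probabilities, and audits folds", {
  sim <- cached_sim("ppmi_like", n = 150, seed = 109)
  st <- suppressWarnings(suppressMessages(fit_progression_stack(
    sim$cohort, sim$geno, sim$weights_pd, sim$weights_ea, sim$carriers,
    n_trials = 2, nrounds = 30, n_folds = 3, seed = 5)))
  expect_s3_class(st, "prog_stack")
  expect_setequal(names(st$submodels),
                  c(t(outer(c("I", "II", "III"), c(12, 24, 36),
                            paste, sep = "_"))))
  expect_setequal(names(st$direct), paste0("Total_", c(12, 24, 36)))
  # out-of-fold audit: every labelled subject has a fold assignment and
  # an out-of-fold probability in [0, 1]
  for (key in names(st$submodels)) {
    sm <- st$submodels[[key]]
    expect_true(all(sm$fold %in% seq_len(3)))
    expect_true(all(sm$oof >= 0 & sm$oof <= 1, na.rm = TRUE))
  }
  # prediction on a new cohort: probabilities in range, aligned to subjects
  simB <- cached_sim("pdbp_like", n = 120, seed = 108)
  pr <- predict(st, simB$cohort, simB$geno, simB$weights_pd,
                simB$weights_ea, simB$carriers)
  expect_equal(nrow(pr), 120)
  prob_cols <- setdiff(names(pr), "subject_id")
  for (cl in prob_cols) {
    expect_true(all(pr[[cl]] >= 0 & pr[[cl]] <= 1))
  }
  # printing and summarizing work
  expect_output(print(st), "prog_stack")
  expect_output(print(summary(st)), "Meta-model")
})

test_that("ablation drops a class (and warns when the class is absent)", {
  sim <- cached_sim("ppmi_like", n = 150, seed = 109)
  st <- suppressWarnings(suppressMessages(fit_progression_stack(
    sim$cohort, sim$geno, sim$weights_pd, sim$weights_ea, sim$carriers,
    n_trials = 2, nrounds = 30, n_folds = 3, seed = 5,
    drop_class = "genetic")))
  expect_false(any(st$schema$class == "genetic"))
  expect_false(any(grepl("^prs_", unlist(lapply(st$submodels,
                                                `[[`, "features")))))
  expect_error(suppressMessages(fit_progression_stack(
    sim$cohort, drop_class = "not_a_class", n_trials = 1, nrounds = 10)),
    "unknown feature class")
  # imaging ablation on an imaging-free cohort is a no-op with a warning
  simB <- cached_sim("pdbp_like", n = 120, seed = 108)
  expect_warning(suppressMessages(fit_progression_stack(
    simB$cohort, n_trials = 1, nrounds = 10, n_folds = 2,
    drop_class = "imaging", seed = 6)), "no-op")
})
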
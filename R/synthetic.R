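# Synthetic paired-cohort generator.
#
# Emulates two Parkinson's observational cohorts (a PPMI-like training
# cohort with DaTScan imaging and low medication exposure, and a PDBP-like
# testing cohort without imaging and with high medication exposure) with a
# planted, configurable effect structure:
#
#   * three latent progression subtypes (motor catch-up, non-motor
#     catch-up, non-progressor) controlling baseline severity and
#     first-interval slopes, producing the "catch-up" pattern: low baseline
#     impairment in the target subpart plus higher impairment in the
#     non-target subparts predicts that subpart's short-term progression;
#   * piecewise-linear latent subpart trajectories over 0-12, 12-24 and
#     24-36 months with regression to the mean after the first interval;
#   * a protective Parkinson's polygenic risk score effect on motor
#     (MDS-UPDRS II/III) progression and an educational-attainment score
#     effect on MDS-UPDRS III progression, both acting through genotypes
#     that are actually scored by the genetics module;
#   * constant medication masking of observed scores for treated subjects;
#   * configurable per-feature missingness and visit dropout.
#
# Ground truth (subtype, latent slopes, standardized scores) is retained in
# a side table consumed only by tests and reports, never by the pipeline.

#' Simulation configuration for a synthetic cohort
#'
#' @param n_subjects cohort size.
#' @param visit_months ordered visit grid in months; must include 0, 12,
#'   24, 36.
#' @param prevalence target fraction of 12-month MDS-UPDRS Total
#'   progressors (0.64 mirrors a PPMI-like case mix, 0.48 a PDBP-like one).
#' @param subtype_mix optional named proportions
#'   (`motor_catch_up`, `nonmotor_catch_up`, `non_progressor`) summing to 1;
#'   by default derived from `prevalence`.
#' @param effect_sizes named signed coefficients:
#'   `pd_prs_motor` (points/year of MDS-UPDRS III slope per SD of PD PRS;
#'   also applied at 40% strength to MDS-UPDRS II), `ea_prs_updrs3`,
#'   `baseline_target` (own-subpart baseline to own slope, negative =
#'   catch-up), `baseline_nontarget` (other-subpart baseline to slope,
#'   positive = catch-up), `age_slope`, `monogenic_updrs3`.
#' @param treatment_model list with `p_treated` (Bernoulli probability of
#'   being treated at any point, independent of progression) and
#'   `mask_offsets` (score-scale shifts applied to treated subjects'
#'   observed scores; defaults -0.67, -1.5, -3.67 for subparts I, II, III).
#' @param noise_sd per-subpart visit-level measurement noise SD.
#' @param slope_sd per-subpart SD of the subject-level random slope in the
#'   first interval.
#' @param missingness named per-feature missing rates applied to the
#'   subject table (see [inject_missingness()]).
#' @param p_visit_missing probability that a non-baseline visit is skipped.
#' @param p_monogenic fraction of monogenic (GBA/LRRK2/SNCA) carriers.
#' @param imaging_available if FALSE, DaTScan columns are absent (PDBP
#'   analog).
#' @param age_mean,sex_p_female demographic mix (mean age in years,
#'   probability of female sex).
#' @param baseline_shift named per-subpart additive shift of the baseline
#'   severity means (the PDBP-like profile is more impaired at baseline);
#'   slopes and labels are unaffected because the catch-up couplings act
#'   on cohort-centered baselines.
#' @param n_block_variants,block_size extra unscored variants simulated in
#'   linkage blocks so QC and LD pruning have real work to do.
#' @param seed integer seed; equal seeds give byte-identical cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 500,
                       visit_months = c(0, 6, 12, 18, 24, 30, 36),
                       prevalence = 0.64,
                       subtype_mix = NULL,
                       effect_sizes = c(pd_prs_motor = -2.4,
                                        ea_prs_updrs3 = 1.2,
                                        baseline_target = -0.30,
                                        baseline_nontarget = 0.10,
                                        age_slope = -0.02,
                                        moca_updrs1 = -0.50,
                                        seadl_updrs2 = -0.18,
                                        monogenic_updrs3 = -0.5),
                       treatment_model = list(
                         p_treated = 0.25,
                         mask_offsets = c(I = -0.67, II = -1.5, III = -3.67)),
                       noise_sd = c(I = 1.3, II = 1.4, III = 2.6),
                       slope_sd = c(I = 1.1, II = 1.1, III = 2.2),
                       missingness = c(moca = 0.05, seadl = 0.05, ess = 0.60,
                                       sbr_caudate_l = 0.10,
                                       sbr_caudate_r = 0.10,
                                       sbr_putamen_l = 0.10,
                                       sbr_putamen_r = 0.10),
                       p_visit_missing = 0.03,
                       p_monogenic = 0.30,
                       imaging_available = TRUE,
                       age_mean = 62, sex_p_female = 0.40,
                       baseline_shift = c(I = 0, II = 0, III = 0),
                       n_block_variants = 120, block_size = 6,
                       seed = 1) {
  if (!all(c(0, 12, 24, 36) %in% visit_months)) {
    config_error("visit_months must include 0, 12, 24 and 36")
  }
  if (is.unsorted(visit_months, strictly = TRUE)) {
    config_error("visit_months must be strictly increasing")
  }
  check_rates(prevalence, "prevalence")
  if (is.null(subtype_mix)) {
    # split the progressor mass 5:3 between motor and non-motor catch-up;
    # slight inflation compensates the (approximately symmetric) label
    # flips induced by slope and measurement noise
    p <- min(0.95, prevalence * 1.06)
    subtype_mix <- c(motor_catch_up = 0.625 * p,
                     nonmotor_catch_up = 0.375 * p,
                     non_progressor = 1 - p)
  }
  if (abs(sum(subtype_mix) - 1) > 1e-8 || any(subtype_mix < 0)) {
    config_error("subtype_mix proportions must be nonnegative and sum to 1")
  }
  need <- c("motor_catch_up", "nonmotor_catch_up", "non_progressor")
  if (!all(need %in% names(subtype_mix))) {
    config_error("subtype_mix must name: %s", paste(need, collapse = ", "))
  }
  check_rates(treatment_model$p_treated, "p_treated")
  check_rates(missingness, "missingness")
  check_rates(p_visit_missing, "p_visit_missing")
  check_rates(p_monogenic, "p_monogenic")
  check_rates(sex_p_female, "sex_p_female")
  stopifnot(n_subjects >= 10, all(noise_sd >= 0), all(slope_sd >= 0),
            all(c("I", "II", "III") %in% names(baseline_shift)))
  structure(list(n_subjects = n_subjects, visit_months = visit_months,
                 prevalence = prevalence, subtype_mix = subtype_mix,
                 effect_sizes = effect_sizes,
                 treatment_model = treatment_model, noise_sd = noise_sd,
                 slope_sd = slope_sd, missingness = missingness,
                 p_visit_missing = p_visit_missing,
                 p_monogenic = p_monogenic,
                 imaging_available = imaging_available,
                 age_mean = age_mean, sex_p_female = sex_p_female,
                 baseline_shift = baseline_shift,
                 n_block_variants = n_block_variants,
                 block_size = block_size, seed = seed),
            class = "sim_config")
}

#' Shorthand cohort profiles
#'
#' `"ppmi_like"` is the training profile (imaging available, low treatment
#' exposure, 64% 12-month Total progressors, 30% monogenic carriers);
#' `"pdbp_like"` is the external-testing profile (no imaging, 75% treated,
#' 48% progressors, 9% carriers).
#'
#' @param profile one of "ppmi_like", "pdbp_like".
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
cohort_profile <- function(profile = c("ppmi_like", "pdbp_like"), ...) {
  profile <- match.arg(profile)
  defaults <- if (profile == "ppmi_like") {
    list()
  } else {
    list(prevalence = 0.48, imaging_available = FALSE,
         p_monogenic = 0.09, age_mean = 60, sex_p_female = 0.65,
         baseline_shift = c(I = 0.5, II = 1, III = 3),
         treatment_model = list(p_treated = 0.75,
                                mask_offsets = c(I = -0.67, II = -1.5,
                                                 III = -3.67)),
         missingness = c(moca = 0.05, seadl = 0.05, ess = 0.60))
  }
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' Longitudinal cohort container
#'
#' @param subjects subject-level table; must contain `subject_id` and
#'   `treated_any`.
#' @param visits visit-level table with `subject_id`, `month`, item
#'   columns (`updrs1_1`, ...), subpart sums (`updrs1`, `updrs2`,
#'   `updrs3`) and `updrs_total`.
#' @param imaging_available logical.
#' @param truth optional hidden ground-truth table (tests only).
#' @return object of class `pd_cohort`.
#' @export
pd_cohort <- function(subjects, visits, imaging_available = TRUE,
                      truth = NULL) {
  stopifnot(is.data.frame(subjects), is.data.frame(visits))
  stopifnot(all(c("subject_id", "treated_any") %in% names(subjects)))
  need <- c("subject_id", "month", "updrs1", "updrs2", "updrs3",
            "updrs_total")
  stopifnot(all(need %in% names(visits)))
  if (anyDuplicated(visits[, c("subject_id", "month")])) {
    config_error("duplicate (subject, month) visit rows")
  }
  tot <- visits$updrs1 + visits$updrs2 + visits$updrs3
  if (max(abs(tot - visits$updrs_total)) > 1e-8) {
    config_error("updrs_total must equal updrs1 + updrs2 + updrs3")
  }
  for (p in 1:3) {
    item_cols <- grep(sprintf("^updrs%d_", p), names(visits), value = TRUE)
    if (length(item_cols) > 0) {
      s <- rowSums(visits[item_cols])
      if (max(abs(s - visits[[sprintf("updrs%d", p)]])) > 1e-8) {
        config_error("updrs%d must equal the sum of its item responses", p)
      }
    }
  }
  structure(list(subjects = subjects, visits = visits,
                 imaging_available = imaging_available, truth = truth,
                 adjusted = FALSE),
            class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("pd_cohort: %d subjects, %d visits (%s imaging)%s\n",
              nrow(x$subjects), nrow(x$visits),
              if (x$imaging_available) "with" else "without",
              if (isTRUE(x$adjusted)) ", medication-adjusted" else ""))
  invisible(x)
}

# latent trajectory parameters of the generator: baseline means/SDs per
# subtype and subpart, first-interval slope means, and the
# mean-reversion/drift structure of later intervals (points/year)
sim_trajectory_params <- function() {
  list(
    baseline_mean = list(
      I   = c(motor_catch_up = 5.2, nonmotor_catch_up = 3.0, non_progressor = 4.6),
      II  = c(motor_catch_up = 3.3, nonmotor_catch_up = 4.6, non_progressor = 4.2),
      III = c(motor_catch_up = 16.0, nonmotor_catch_up = 22.0, non_progressor = 21.0)),
    baseline_sd = c(I = 1.8, II = 1.8, III = 5.0),
    slope1_mean = list(
      I   = c(motor_catch_up = 2.0, nonmotor_catch_up = 5.2, non_progressor = -2.8),
      II  = c(motor_catch_up = 2.8, nonmotor_catch_up = 1.6, non_progressor = -2.6),
      III = c(motor_catch_up = 7.5, nonmotor_catch_up = 2.0, non_progressor = -5.8)),
    # loading of the shared subject-level progression factor (standard
    # normal) on each subpart's first-interval slope; couples the subpart
    # labels so their overlap matches observational cohorts
    shared_loading = c(I = 2.2, II = 1.5, III = 2.5),
    # later intervals: the persistent (subtype/covariate-driven) slope
    # component carries forward at reduced strength while the transient
    # component mean-reverts, so cumulative slopes over longer horizons
    # are cleaner readouts of the underlying progression propensity
    # s2 = drift2 + persist2 * D - revert * T + noise
    # s3 = drift3 + persist3 * D + noise      (D persistent, T transient)
    drift2 = c(I = 0.4, II = 0.4, III = 1.0),
    revert = 0.45,
    persist2 = 0.35,
    drift3 = c(I = 0.3, II = 0.3, III = 0.8),
    persist3 = 0.30,
    later_noise_frac = 0.7,
    n_items = c(I = 13, II = 13, III = 33)
  )
}

# draw genotypes + weight tables; scored variants are independent of the
# linkage blocks, a handful of block variants are planted to fail QC
simulate_genotypes <- function(n, cfg) {
  alleles <- c("A", "C", "G", "T")
  # non-palindromic ref/alt pairs only, so scoring never skips them
  pairs <- expand.grid(ref = alleles, alt = alleles,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt &
                   !is_palindromic(pairs$ref, pairs$alt), ]
  draw_pair <- function(k) pairs[sample.int(nrow(pairs), k, replace = TRUE), ]

  n_pd <- 90; n_ea <- 763
  n_blk <- cfg$n_block_variants
  p_total <- n_pd + n_ea + n_blk

  maf_pd <- stats::runif(n_pd, 0.05, 0.5)
  maf_ea <- stats::runif(n_ea, 0.05, 0.5)
  g_pd <- matrix(stats::rbinom(n * n_pd, 2, rep(maf_pd, each = n)), nrow = n)
  g_ea <- matrix(stats::rbinom(n * n_ea, 2, rep(maf_ea, each = n)), nrow = n)

  # linkage blocks: each variant copies the block haplotype dosage, with a
  # 10% per-subject chance of an independent redraw
  n_blocks <- ceiling(n_blk / cfg$block_size)
  g_blk <- matrix(0, nrow = n, ncol = n_blk)
  for (b in seq_len(n_blocks)) {
    p_b <- stats::runif(1, 0.1, 0.5)
    core <- stats::rbinom(n, 2, p_b)
    for (k in seq_len(cfg$block_size)) {
      j <- (b - 1) * cfg$block_size + k
      if (j > n_blk) break
      flip <- stats::runif(n) < 0.10
      g_blk[, j] <- ifelse(flip, stats::rbinom(n, 2, p_b), core)
    }
  }
  # planted QC failures among block variants: low call rate, monomorphic,
  # gross Hardy-Weinberg violation
  if (n_blk >= 6) {
    g_blk[stats::runif(n) < 0.10, 1] <- NA  # call rate ~0.90 < 0.95
    g_blk[, 2] <- 0                          # monomorphic
    g_blk[, 3] <- 1                          # all-het: HWE p << 1e-15
  }

  dosage <- cbind(g_pd, g_ea, g_blk)
  ids <- c(sprintf("pd_snp_%03d", seq_len(n_pd)),
           sprintf("ea_snp_%03d", seq_len(n_ea)),
           sprintf("blk_snp_%03d", seq_len(n_blk)))
  pr <- draw_pair(p_total)
  variants <- data.frame(id = ids,
                         chrom = rep(1L, p_total),
                         pos = seq_len(p_total) * 1000L,
                         ref = pr$ref, alt = pr$alt,
                         stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("S%04d", seq_len(n))
  geno <- genotype_data(dosage, variants)
  list(
    geno = geno,
    weights_pd = weight_table(ids[seq_len(n_pd)],
                              variants$alt[seq_len(n_pd)],
                              stats::rnorm(n_pd, 0, 0.15), name = "pd"),
    weights_ea = weight_table(ids[n_pd + seq_len(n_ea)],
                              variants$alt[n_pd + seq_len(n_ea)],
                              stats::rnorm(n_ea, 0, 0.03), name = "ea")
  )
}

# allocate an integer subpart sum to item responses by multinomial split
# with fixed uneven item probabilities
allocate_items <- function(scores, n_items) {
  probs <- seq_len(n_items)
  probs <- probs / sum(probs)
  out <- matrix(0L, nrow = length(scores), ncol = n_items)
  pos <- which(scores > 0)
  if (length(pos) > 0) {
    draws <- vapply(scores[pos],
                    function(s) stats::rmultinom(1, s, probs)[, 1],
                    integer(n_items))
    out[pos, ] <- t(draws)
  }
  out
}

#' Generate a synthetic cohort with genotypes
#'
#' Draws a full longitudinal cohort plus genotype data from a
#' [sim_config()]. Deterministic given the config seed. The planted ground
#' truth (subtype, latent slopes, standardized polygenic scores) is kept in
#' `$truth`, which the analysis pipeline never reads.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (a [pd_cohort()]), `geno`
#'   (a [genotype_data()]), `weights_pd`, `weights_ea`
#'   ([weight_table()]s) and `carriers` (monogenic carrier calls).
#' @examples
#' sim <- generate_cohort(sim_config(n_subjects = 50, seed = 7))
#' sim$cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  tp <- sim_trajectory_params()
  ids <- sprintf("S%04d", seq_len(n))

  subtype <- sample(names(cfg$subtype_mix), n, replace = TRUE,
                    prob = cfg$subtype_mix)
  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, 9), 35), 88)
  sex <- stats::rbinom(n, 1, cfg$sex_p_female)  # 1 = female
  education <- pmax(8, round(stats::rnorm(n, 15, 3)))

  gsim <- simulate_genotypes(n, cfg)
  z_pd <- as.numeric(scale(compute_prs(gsim$geno, gsim$weights_pd)$score))
  z_ea <- as.numeric(scale(compute_prs(gsim$geno, gsim$weights_ea)$score))

  mono_any <- stats::rbinom(n, 1, cfg$p_monogenic)
  gene_pick <- sample(c("GBA", "LRRK2", "SNCA"), n, replace = TRUE,
                      prob = c(0.5, 0.4, 0.1))
  carriers <- data.frame(subject_id = ids,
                         GBA = mono_any == 1 & gene_pick == "GBA",
                         LRRK2 = mono_any == 1 & gene_pick == "LRRK2",
                         SNCA = mono_any == 1 & gene_pick == "SNCA",
                         stringsAsFactors = FALSE)

  es <- cfg$effect_sizes
  # cognitive and daily-living instruments double as subpart-specific
  # progression drivers, so each subpart has its own predictor family
  moca <- pmin(30L, pmax(0L, as.integer(round(stats::rnorm(n, 27, 2)))))
  seadl <- pmin(100L, pmax(0L, as.integer(round(stats::rnorm(n, 93, 4)))))
  baseline <- list(); s1 <- list(); s2 <- list(); s3 <- list()
  for (p in PARTS) {
    baseline[[p]] <- pmax(0, tp$baseline_mean[[p]][subtype] +
                            cfg$baseline_shift[[p]] +
                            stats::rnorm(n, 0, tp$baseline_sd[[p]]))
  }
  shared <- stats::rnorm(n)  # common transient progression propensity
  for (p in PARTS) {
    # persistent component: subtype structure, catch-up couplings and
    # covariate/genetic effects
    det <- tp$slope1_mean[[p]][subtype] + es[["baseline_target"]] *
      (baseline[[p]] - mean(baseline[[p]]))
    other <- setdiff(PARTS, p)
    nontarget <- Reduce(`+`, lapply(other, function(q) {
      baseline[[q]] - mean(baseline[[q]])
    }))
    det <- det + es[["baseline_nontarget"]] * nontarget
    if (p == "I") {
      det <- det + es[["moca_updrs1"]] * (moca - mean(moca))
    }
    if (p == "III") {
      det <- det + es[["pd_prs_motor"]] * z_pd + es[["ea_prs_updrs3"]] * z_ea +
        es[["monogenic_updrs3"]] * mono_any + es[["age_slope"]] * (age - 62)
    }
    if (p == "II") {
      det <- det + 0.4 * es[["pd_prs_motor"]] * z_pd +
        es[["seadl_updrs2"]] * (seadl - mean(seadl))
    }
    # transient component: shared factor plus subject-level slope noise
    trans <- tp$shared_loading[[p]] * shared +
      stats::rnorm(n, 0, cfg$slope_sd[[p]])
    s1[[p]] <- det + trans
    lsd <- cfg$slope_sd[[p]] * tp$later_noise_frac
    s2[[p]] <- tp$drift2[[p]] + tp$persist2 * det - tp$revert * trans +
      stats::rnorm(n, 0, lsd)
    s3[[p]] <- tp$drift3[[p]] + tp$persist3 * det + stats::rnorm(n, 0, lsd)
  }

  treated <- stats::rbinom(n, 1, cfg$treatment_model$p_treated)
  lev <- as.integer(treated & stats::runif(n) < 0.70)
  ago <- as.integer(treated & stats::runif(n) < 0.45)
  oth <- as.integer(treated & stats::runif(n) < 0.50)
  none <- treated == 1 & lev + ago + oth == 0
  lev[none] <- 1L

  # visit table: latent piecewise-linear value + visit noise, medication
  # masking for treated subjects, clamp at 0, integer scores, item split
  mask <- cfg$treatment_model$mask_offsets
  visit_rows <- list()
  for (m in cfg$visit_months) {
    t1 <- min(m, 12) / 12
    t2 <- min(max(m - 12, 0), 12) / 12
    t3 <- min(max(m - 24, 0), 12) / 12
    row <- data.frame(subject_id = ids, month = m,
                      stringsAsFactors = FALSE)
    for (p in PARTS) {
      latent <- baseline[[p]] + s1[[p]] * t1 + s2[[p]] * t2 + s3[[p]] * t3
      obs <- latent + stats::rnorm(n, 0, cfg$noise_sd[[p]]) +
        mask[[p]] * treated
      row[[PART_COLS[[p]]]] <- pmax(0L, as.integer(round(obs)))
    }
    visit_rows[[as.character(m)]] <- row
  }
  visits <- do.call(rbind, visit_rows)
  # visit dropout (baseline always kept)
  keep <- visits$month == 0 | stats::runif(nrow(visits)) >= cfg$p_visit_missing
  visits <- visits[keep, ]
  for (p in PARTS) {
    items <- allocate_items(visits[[PART_COLS[[p]]]], tp$n_items[[p]])
    colnames(items) <- sprintf("%s_%d", PART_COLS[[p]], seq_len(ncol(items)))
    visits <- cbind(visits, as.data.frame(items))
  }
  visits$updrs_total <- visits$updrs1 + visits$updrs2 + visits$updrs3
  visits <- visits[order(visits$subject_id, visits$month), ]
  rownames(visits) <- NULL

  subjects <- data.frame(
    subject_id = ids, age = round(age, 1), sex = sex,
    education_years = education,
    treated_any = treated, treated_levodopa = lev,
    treated_agonist = ago, treated_other = oth,
    moca = moca,
    seadl = seadl,
    hoehn_yahr = pmin(5, pmax(0, round(1 + baseline[["III"]] / 15 +
                                         stats::rnorm(n, 0, 0.3)))),
    ess = pmin(24L, pmax(0L, as.integer(round(stats::rnorm(n, 8, 4))))),
    stringsAsFactors = FALSE
  )
  if (cfg$imaging_available) {
    caud <- stats::rnorm(n, 2.05, 0.35)
    puta <- stats::rnorm(n, 0.90, 0.25)
    subjects$sbr_caudate_l <- round(pmax(0.2, caud + stats::rnorm(n, 0, 0.05)), 2)
    subjects$sbr_caudate_r <- round(pmax(0.2, caud + stats::rnorm(n, 0, 0.05)), 2)
    subjects$sbr_putamen_l <- round(pmax(0.1, puta + stats::rnorm(n, 0, 0.05)), 2)
    subjects$sbr_putamen_r <- round(pmax(0.1, puta + stats::rnorm(n, 0, 0.05)), 2)
  }

  truth <- data.frame(subject_id = ids, subtype = subtype,
                      z_pd = z_pd, z_ea = z_ea,
                      stringsAsFactors = FALSE)
  for (p in PARTS) {
    truth[[paste0("baseline_", PART_COLS[[p]])]] <- baseline[[p]]
    truth[[paste0("slope1_", PART_COLS[[p]])]] <- s1[[p]]
    truth[[paste0("slope2_", PART_COLS[[p]])]] <- s2[[p]]
    truth[[paste0("slope3_", PART_COLS[[p]])]] <- s3[[p]]
  }
  # declared planted structure, consumed by tests and audits only: the
  # strongest feature class is the physician exam (the catch-up subtype
  # structure lives in the baseline motor exam), imaging carries no
  # planted signal, and the listed features all carry substantive planted
  # effects on 12-month Total progression
  attr(truth, "informative_features") <-
    c("updrs1", "updrs2", "updrs3", "updrs_total", "prs_pd", "prs_ea")
  attr(truth, "strongest_class") <- "physician-exam"
  attr(truth, "null_class") <- "imaging"

  cohort <- pd_cohort(subjects, visits,
                      imaging_available = cfg$imaging_available,
                      truth = truth)
  cohort <- inject_missingness(cohort, cfg$missingness,
                               seed = stage_seed(cfg$seed, 17))
  list(cohort = cohort, geno = gsim$geno,
       weights_pd = gsim$weights_pd, weights_ea = gsim$weights_ea,
       carriers = carriers)
}

#' Inject missing values into subject-level features
#'
#' Sets each named feature to NA independently with the requested rate.
#' Only subject-table feature columns may be named; the longitudinal
#' MDS-UPDRS endpoints used for labelling are never touched.
#'
#' @param cohort a `pd_cohort`.
#' @param rates named vector of per-feature missing rates in \[0, 1\];
#'   names absent from the subject table are ignored with a message (e.g.
#'   imaging rates on an imaging-free cohort).
#' @param seed integer seed.
#' @return the cohort with NAs injected.
#' @export
inject_missingness <- function(cohort, rates, seed = 1) {
  stopifnot(inherits(cohort, "pd_cohort"))
  if (length(rates) == 0) return(cohort)
  check_rates(rates, "missingness rates")
  if (is.null(names(rates))) config_error("missingness rates must be named")
  protected <- c("subject_id", "treated_any")
  if (any(names(rates) %in% protected)) {
    config_error("cannot inject missingness into: %s",
                 paste(intersect(names(rates), protected), collapse = ", "))
  }
  absent <- setdiff(names(rates), names(cohort$subjects))
  if (length(absent) > 0) {
    message(sprintf("missingness rates for absent column(s) ignored: %s",
                    paste(absent, collapse = ", ")))
  }
  set.seed(seed)
  for (nm in intersect(names(rates), names(cohort$subjects))) {
    if (rates[[nm]] <= 0) next
    hit <- stats::runif(nrow(cohort$subjects)) < rates[[nm]]
    cohort$subjects[[nm]][hit] <- NA
  }
  cohort
}

#' Subset a simulated cohort (and its genetic data) to given subjects
#'
#' Utility for train/test-split experiments within one cohort: restricts
#' the cohort tables, genotype rows, carrier calls and the hidden truth
#' table to the requested subject ids.
#'
#' @param sim a [generate_cohort()] result or a bare `pd_cohort`.
#' @param ids subject ids to keep.
#' @return an object of the same shape as `sim`.
#' @export
subset_cohort <- function(sim, ids) {
  take <- function(cohort) {
    cohort$subjects <- cohort$subjects[cohort$subjects$subject_id %in% ids, ]
    cohort$visits <- cohort$visits[cohort$visits$subject_id %in% ids, ]
    if (!is.null(cohort$truth)) {
      cohort$truth <- cohort$truth[cohort$truth$subject_id %in% ids, ]
    }
    cohort
  }
  if (inherits(sim, "pd_cohort")) return(take(sim))
  sim$cohort <- take(sim$cohort)
  if (!is.null(sim$geno)) {
    keep <- rownames(sim$geno$dosage) %in% ids
    sim$geno <- genotype_data(sim$geno$dosage[keep, , drop = FALSE],
                              sim$geno$variants)
  }
  if (!is.null(sim$carriers)) {
    sim$carriers <- sim$carriers[sim$carriers$subject_id %in% ids, ]
  }
  sim
}

#' Write a cohort (and optional genotypes) as delimited text
#'
#' Writes `subjects.tsv`, `visits.tsv` and, when present, `truth.tsv`
#' (ground truth; for tests and audits only). With genotype data also
#' writes `dosage.tsv`, `variants.tsv` and the weight tables.
#'
#' @param sim a [generate_cohort()] result or a bare `pd_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (inherits(sim, "pd_cohort")) sim else sim$cohort
  w <- function(x, f) {
    path <- file.path(dir, f)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(w(cohort$subjects, "subjects.tsv"),
             w(cohort$visits, "visits.tsv"))
  if (!is.null(cohort$truth)) files <- c(files, w(cohort$truth, "truth.tsv"))
  if (!inherits(sim, "pd_cohort") && !is.null(sim$geno)) {
    dos <- data.frame(subject_id = rownames(sim$geno$dosage),
                      sim$geno$dosage, check.names = FALSE)
    files <- c(files, w(dos, "dosage.tsv"),
               w(sim$geno$variants, "variants.tsv"),
               w(sim$weights_pd, "weights_pd.tsv"),
               w(sim$weights_ea, "weights_ea.tsv"),
               w(sim$carriers, "carriers.tsv"))
  }
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `subjects.tsv` and `visits.tsv`.
#' @param imaging_available logical; defaults to whether DaTScan columns
#'   are present.
#' @return a [pd_cohort()].
#' @export
read_cohort <- function(dir, imaging_available = NULL) {
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  visits <- utils::read.delim(file.path(dir, "visits.tsv"),
                              stringsAsFactors = FALSE)
  if (is.null(imaging_available)) {
    imaging_available <- "sbr_putamen_l" %in% names(subjects)
  }
  pd_cohort(subjects, visits, imaging_available = imaging_available)
}
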
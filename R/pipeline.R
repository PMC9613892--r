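# End-to-end pipeline: simulate (or load) paired cohorts, QC and score
# genotypes, label progression, fit the stacked meta-predictor on the
# training cohort, evaluate on the held-out external cohort, run the
# feature-class ablations and the trial-enrichment power calculation,
# writing every stage artifact plus a manifest into one run directory.

#' Declarative configuration for a full pipeline run
#'
#' @param n_train,n_test cohort sizes (training is PPMI-like with imaging,
#'   testing PDBP-like without).
#' @param n_trials randomized-search draws per model.
#' @param top_k features kept per model.
#' @param n_folds stacking folds.
#' @param nrounds maximum boosting rounds.
#' @param horizons label horizons in months.
#' @param target_horizon meta-prediction horizon.
#' @param ablations feature classes to ablate (possibly empty).
#' @param power list with `p_control`, `rrr`, `alpha`, `power`,
#'   `enriched_p_control` for the trial-enrichment calculation.
#' @param seed global seed; fans out to per-stage seeds via
#'   [stage_seed()].
#' @return list of class `run_config`.
#' @export
run_config <- function(n_train = 500, n_test = 350, n_trials = 25,
                       top_k = 25, n_folds = 5, nrounds = 150,
                       horizons = c(12, 24, 36), target_horizon = 12,
                       ablations = c("genetic", "physician-exam",
                                     "survey", "imaging"),
                       power = list(p_control = 0.5, rrr = 0.10,
                                    alpha = 0.05, power = 0.80,
                                    enriched_p_control = 0.75),
                       seed = 1) {
  stopifnot(target_horizon %in% horizons)
  bad <- setdiff(ablations, FEATURE_CLASSES)
  if (length(bad) > 0) config_error("unknown ablation class(es): %s",
                                    paste(bad, collapse = ", "))
  structure(list(n_train = n_train, n_test = n_test, n_trials = n_trials,
                 top_k = top_k, n_folds = n_folds, nrounds = nrounds,
                 horizons = horizons, target_horizon = target_horizon,
                 ablations = ablations, power = power, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    config_error("reading YAML configs requires the 'yaml' package")
  }
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate the paired cohorts; genotype QC, LD pruning
#' and polygenic scoring; medication-offset estimation and progression
#' labelling; stacked model training on the training cohort; evaluation on
#' the internal held-out split and the external cohort; feature-class
#' ablations; trial-enrichment power calculation. Every stage writes its
#' artifact under `out_dir`, and `manifest.json` records the configuration
#' hash, seed, package version and the checksum of every output, so a
#' rerun with an identical configuration reproduces an identical manifest.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir output directory.
#' @return invisibly, a list with the fitted stack, evaluations, ablation
#'   metrics, power results and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("pdrun")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  files <- character(0)

  # --- stage 1: simulate paired cohorts -------------------------------
  simA <- generate_cohort(cohort_profile(
    "ppmi_like", n_subjects = config$n_train,
    seed = stage_seed(seed, 1)))
  simB <- generate_cohort(cohort_profile(
    "pdbp_like", n_subjects = config$n_test,
    seed = stage_seed(seed, 2)))
  files <- c(files, write_cohort(simA, file.path(out_dir, "cohortA")),
             write_cohort(simB, file.path(out_dir, "cohortB")))

  # --- stage 2: genotype QC, pruning, scoring -------------------------
  qc_mask <- variant_qc(simA$geno)
  qc_tab <- attr(qc_mask, "qc_table")
  kept <- genotype_data(simA$geno$dosage[, qc_mask, drop = FALSE],
                        simA$geno$variants[qc_mask, , drop = FALSE])
  pruned <- ld_prune(kept)
  qc_report <- list(n_variants = length(qc_mask),
                    n_pass_qc = sum(qc_mask),
                    n_after_prune = length(pruned),
                    n_fail_call_rate = sum(qc_tab$call_rate <= 0.95),
                    n_fail_maf = sum(qc_tab$maf <= 0.01),
                    n_fail_hwe = sum(qc_tab$hwe_p <= 1e-15))
  files <- c(files, write_json_artifact(qc_report,
                                        file.path(out_dir, "qc_report.json")))
  prs <- data.frame(subject_id = rownames(simA$geno$dosage),
                    prs_pd = compute_prs(simA$geno, simA$weights_pd)$score,
                    prs_ea = compute_prs(simA$geno, simA$weights_ea)$score)
  prs_path <- file.path(out_dir, "prs_train.tsv")
  utils::write.table(prs, prs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, prs_path)

  # --- stage 3: labels and overlap ------------------------------------
  offsets <- estimate_offsets(simA$cohort)
  labA <- label_progression(apply_adjustment(simA$cohort, offsets),
                            horizons = config$horizons)
  lab_path <- file.path(out_dir, "labels_train.tsv")
  utils::write.table(labA, lab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jac <- jaccard_overlap(labA, config$target_horizon)
  files <- c(files, lab_path,
             write_json_artifact(as.data.frame(jac),
                                 file.path(out_dir, "jaccard.json")))

  # --- stage 4: stacked training on cohort A --------------------------
  stack <- fit_progression_stack(
    simA$cohort, simA$geno, simA$weights_pd, simA$weights_ea,
    simA$carriers, target_horizon = config$target_horizon,
    meta_horizons = config$horizons,
    horizons = config$horizons, top_k = config$top_k,
    n_trials = config$n_trials, n_folds = config$n_folds,
    nrounds = config$nrounds, seed = stage_seed(seed, 3))

  # --- stage 5: evaluation (external cohort B; no refitting) ----------
  evB <- evaluate_stack(stack, simB$cohort, simB$geno, simB$weights_pd,
                        simB$weights_ea, simB$carriers)
  metrics <- list(
    external = list(meta_f1 = evB$meta$f1, meta_roc_auc = evB$meta$roc_auc,
                    meta_pr_auc = evB$meta$pr_auc,
                    direct_f1 = evB$direct$f1,
                    direct_roc_auc = evB$direct$roc_auc,
                    n = evB$meta$n),
    submodel_val_f1 = lapply(stack$submodels, function(s) s$val_f1),
    direct_val_f1 = lapply(stack$direct, function(s) s$val_f1),
    meta_val_f1 = lapply(stack$metas, function(s) s$val_f1))
  files <- c(files, write_json_artifact(metrics,
                                        file.path(out_dir, "metrics.json")))

  # --- stage 6: ablations ---------------------------------------------
  ablations <- list()
  for (cl in config$ablations) {
    st_a <- withCallingHandlers(
      fit_progression_stack(
        simA$cohort, simA$geno, simA$weights_pd, simA$weights_ea,
        simA$carriers, target_horizon = config$target_horizon,
        horizons = config$horizons, top_k = config$top_k,
        n_trials = config$n_trials, n_folds = config$n_folds,
        nrounds = config$nrounds, drop_class = cl,
        seed = stage_seed(seed, 3)),
      warning = function(w) invokeRestart("muffleWarning"))
    ev_a <- evaluate_stack(st_a, simB$cohort, simB$geno, simB$weights_pd,
                           simB$weights_ea, simB$carriers)
    ablations[[cl]] <- list(meta_roc_auc = ev_a$meta$roc_auc,
                            meta_pr_auc = ev_a$meta$pr_auc,
                            delta_roc_auc = ev_a$meta$roc_auc -
                              evB$meta$roc_auc)
  }
  files <- c(files, write_json_artifact(ablations,
                                        file.path(out_dir, "ablation.json")))

  # --- stage 7: trial-enrichment power calculation --------------------
  pw <- config$power
  cfg_pw <- power_calc_config(pw$p_control, pw$rrr, pw$alpha, pw$power)
  gain <- enrichment_gain(cfg_pw, pw$enriched_p_control)
  power_out <- c(required_sample_size(cfg_pw)[c("n_per_arm", "n_total")],
                 gain)
  files <- c(files, write_json_artifact(power_out,
                                        file.path(out_dir, "power.json")))

  # --- manifest --------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.json")
  write_json_artifact(unclass(config), cfg_file)
  files <- c(files, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pdstack")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = as.list(stats::setNames(tools::md5sum(sort(files)),
                                      basename(sort(files)))))
  write_json_artifact(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(stack = stack, external_eval = evB, metrics = metrics,
                 ablations = ablations, power = power_out,
                 jaccard = jac, qc = qc_report, manifest = manifest,
                 out_dir = out_dir, simA = simA, simB = simB))
}
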
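# pdstack

Genetically informed prediction of short-term Parkinson's disease (PD)
progression, and the trial-enrichment arithmetic it enables.

## The problem

In observational PD cohorts, only some patients progress over a
12-month window, and *which* scale they progress on — the physician
motor exam (MDS-UPDRS Part III), self-reported motor experiences
(Part II) or non-motor experiences (Part I) — is heterogeneous: the
overlap between subpart progressor sets is only ~50–60% (Jaccard). A
trial with a progression endpoint that enrolls unselected patients
spends most of its sample on people who were never going to progress
during the trial.

`pdstack` implements the full analysis path:

1. **Labelling** — medication-adjusted progressor status. Treated
   subjects' MDS-UPDRS scores are masked by symptomatic therapy; a
   constant per-subpart offset (the training-cohort mean
   untreated-minus-treated difference, reference values +0.67 / +1.5 /
   +3.67 for Parts I/II/III) is added to treated subjects' scores.
   A subject is a progressor for a target (I, II, III, Total) and
   horizon (12/24/36 months) iff the annualized two-endpoint slope of
   the adjusted score is strictly positive — twelve labels per subject.
2. **Genetics** — variant QC (call rate > 95%, HWE p > 1e−15,
   MAF > 1%), LD pruning (window 50, step 5, r² 0.2), a 7-SD ancestry
   window on the first 6 genetic principal components, weighted
   allele-counting polygenic scores (90-SNP PD risk, 763-SNP educational
   attainment) and GBA/LRRK2/SNCA monogenic flags.
3. **Features** — >50%-missingness filter, typed imputation
   (mean/median/mode), train-anchored standard scaling, and Shapley
   (exact tree-path) feature ranking with top-25 selection.
4. **Stacked meta-prediction** — nine DART gradient-boosted submodels
   (subpart × horizon) tuned by randomized search over wide
   standard ranges; their out-of-fold probabilities join the selected baseline
   features as inputs to a boosted meta-model of 12-month Total
   progression:

   `S_j = Σ_i β_i g_ij` (polygenic score),
   `slope_h = (x(h) − x(0)) / (h/12)` (label),
   `meta: P(progressor) = f(p_I,12 , …, p_III,36 , x_baseline)`.

5. **Evaluation & ablation** — F1 / ROC AUC / PR AUC with bootstrap
   intervals, Wilcoxon rank-sum group comparisons, PRS distribution
   contrasts by progression status, and feature-class ablation
   (genetic / physician-exam / survey / imaging).
6. **Trial enrichment** — the pooled two-proportion sample-size formula
   `n/arm = (z_{1−α/2}√(2p̄q̄) + z_{1−β}√(p₁q₁+p₂q₂))² / (p₁−p₂)²`,
   and the gain from enriching enrollment with predicted progressors.

The real AMP-PD (PPMI/PDBP) datasets are access-controlled, so the
package ships a synthetic paired-cohort generator
(`generate_cohort()`, `cohort_profile()`) with planted effect structure
— catch-up progression subtypes, a protective PD polygenic score effect
on motor progression, medication masking, missingness, and a PDBP-like
external cohort with covariate shift and no imaging — so the entire
pipeline is testable end to end. See `vignettes/methods.Rmd` for the
model and every design decision.

## Worked example

```r
library(pdstack)

# a PPMI-like training cohort and a PDBP-like external cohort
simA <- generate_cohort(cohort_profile("ppmi_like", n_subjects = 600, seed = 101))
simB <- generate_cohort(cohort_profile("pdbp_like", n_subjects = 600, seed = 202))

# medication adjustment offsets estimated from the training cohort
estimate_offsets(simA$cohort)
#> medication-adjustment offsets: I +1.492, II +1.612, III +4.966

# fit the stacked meta-predictor (9 submodels + direct models + meta)
stack <- fit_progression_stack(simA$cohort, simA$geno, simA$weights_pd,
                               simA$weights_ea, simA$carriers,
                               n_trials = 8, nrounds = 120, seed = 7)
stack
#> Stacked progression meta-predictor (prog_stack)
#>   training subjects: 600; target: 12-month MDS-UPDRS Total
#>   submodels: I_12 I_24 I_36 II_12 II_24 II_36 III_12 III_24 III_36
#>   meta validation F1 = 0.759 (internal split)

# external evaluation: no transform or model is refitted
ev <- evaluate_stack(stack, simB$cohort, simB$geno, simB$weights_pd,
                     simB$weights_ea, simB$carriers)
ev$meta
#> classification metrics (n = 583, prevalence = 0.50)
#>   F1 = 0.649  ROC AUC = 0.643  PR AUC = 0.654
#>   confusion: TP=221 FP=166 FN=73 TN=123

# trial-enrichment arithmetic
cfg <- power_calc_config(p_control = 0.5, rrr = 0.10)
required_sample_size(cfg)$n_total          # 3130 — "just over 3000"
enrichment_gain(cfg, 0.75)                 # 1142 enriched, ratio 0.365
```

The estimated offsets recover the sign and rough magnitude of the
generator's planted medication masking (+0.67/+1.5/+3.67; the
between-subject score variance puts an SE of roughly 0.3-0.6 points on
each at this cohort size); the external metrics sit in
the regime the generator's noise budget allows (the interesting claims
— meta ≥ direct, ablation ordering, planted-sign recovery — are
property-checked in `tests/testthat/test-acceptance.R`). Exact numbers
above are what the code prints for those seeds.

A one-command end-to-end run (simulate → QC/PRS → label → train → meta
→ evaluate → ablate → power) with a manifest of artifact checksums:

```r
res <- run_pipeline(run_config(n_train = 500, n_test = 350, seed = 1),
                    out_dir = "pdstack_run")
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --config cfg.yaml
--out run_dir --seed 1`.

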
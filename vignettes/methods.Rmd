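---
title: "Methods: genetically informed meta-prediction of short-term Parkinson's progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically informed meta-prediction of short-term Parkinson's progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Short-term progression in Parkinson's disease (PD) is heterogeneous:
over a 12-month window some patients worsen on the physician motor exam
(MDS-UPDRS Part III), others on self-reported motor or non-motor scales
(Parts II and I), and many do not worsen at all. A clinical trial with a
progression endpoint wastes most of its sample on enrollees who were
never going to progress during the trial. `pdstack` implements a
pipeline that (i) labels progressors from longitudinal MDS-UPDRS scores
after correcting for symptomatic medication, (ii) predicts 12-month
MDS-UPDRS Total progression from baseline-only clinical, imaging and
genetic features through a stacked ensemble of subpart-by-horizon
submodels, and (iii) converts the resulting enrichment capability into
trial sample-size arithmetic.

Because the motivating patient-level datasets (PPMI- and PDBP-style
observational cohorts) are access-controlled, the package ships a
synthetic paired-cohort generator with a planted, configurable effect
structure. Every claim the test-suite makes is a claim about recovery
of structure that the generator provably put in.

# Progressor labelling

Observed MDS-UPDRS scores of treated subjects are masked downward by
symptomatic medication. `estimate_offsets()` computes, per subpart, the
mean score of untreated minus treated subjects pooled over all visits of
the *training* cohort; `apply_adjustment()` adds these constants to every
visit of treated subjects ("treated" = treated at any point during
follow-up, because visit-level treatment data are unreliable). Since the
offset is constant over time it cancels in any two-endpoint slope:
labels are provably invariant to the adjustment (a property test), but
adjusted score *levels* are what all downstream feature extraction uses.

For each target (Parts I, II, III and Total) and horizon (12, 24, 36
months), the slope is the annualized two-endpoint difference
`(value(h) - value(0)) / (h/12)` using the visit nearest the nominal
month within ±3 months (observational PD cohorts schedule visits
nominally every 6 months with real-world jitter; ±3 months assigns a
nearest visit without ambiguity).
A subject is a **progressor** iff the slope is strictly positive; zero
or negative slopes are non-progressors. Subjects missing an endpoint are
dropped from that target only. Total = I + II + III at every visit, so
the Total slope is identically the sum of the subpart slopes.

`jaccard_overlap()` quantifies the heterogeneity of the twelve labels as
|A∩B|/|A∪B| between progressor sets, and `annualized_trajectory()`
produces the 12-month-lag slope series (value(m) − value(m−12)) used to
visualize regression to the mean.

# Genetics

`variant_qc()` retains variants with call rate > 0.95, Hardy–Weinberg
equilibrium p > 1e−15 and minor allele frequency > 0.01 (all strict).
The HWE test is the 1-df chi-square goodness-of-fit test against
(p², 2pq, q²); at a threshold of 1e−15 the difference from an exact test
is immaterial, and the chi-square form is transparent and testable
against hand-computed oracles. `ld_prune()` slides a 50-variant window
in steps of 5 and greedily removes, from any pair with dosage r² > 0.2,
the member with the lower minor allele frequency (ties remove the later
variant) — deterministic, and verified against an independently written
quadratic-time pruner. `ancestry_filter()` keeps subjects within 7
reference-panel standard deviations of the reference mean on each of the
first 6 genetic principal components (boundary inclusive, reading
"within" as ≤); reference means/SDs are consumed as inputs, never
recomputed from the reference panel.

`compute_prs()` is standard weighted allele counting S_j = Σ β_i g_ij
with the dosage oriented to the effect allele (2 − g when the effect
allele is the reference allele). Missing dosages are imputed as twice
the oriented effect-allele frequency (the usual allelic-score
convention). Palindromic A/T and C/G
variants cannot be strand-resolved by letter matching and are skipped
with a warning rather than guessed. Monogenic risk (GBA, LRRK2, SNCA
carrier status) collapses to one flag per gene plus a combined flag.

# Features

Baseline features are the subject-level instruments (age, sex,
education, MoCA, SE-ADL, Hoehn & Yahr, DaTScan striatal binding ratios
where available), the baseline MDS-UPDRS subpart/Total scores and item
responses, the two polygenic scores (90-SNP PD risk, 763-SNP educational
attainment) and the monogenic flags. The Epworth Sleepiness Scale is
accepted in input but excluded from modelling by default (it contributes
essentially nothing and is heavily missing). Every column carries a type
(continuous / ordinal / categorical) and a feature class (genetic /
physician-exam / survey / imaging / demographic); the shipped
`inst/extdata/feature_schema.tsv` is the column dictionary. The Total
score is tagged physician-exam because the motor exam dominates its
range; Part I/II scores, MoCA and SE-ADL are survey-class.

Columns with > 50% missingness are dropped (strict). Remaining gaps are
imputed by training mean (continuous), median (ordinal) or mode
(categorical), then standardized by the training mean and *population*
standard deviation (the standard-scaler convention, so a two-point
column (1, 3) maps to (−1, 1)). All parameters are fitted on training
rows only and reapplied frozen — a bitwise-identity audit is part of the
test suite.

Feature ranking uses exact tree-path Shapley attributions of a
gradient-boosted explainer (`predcontrib`; additivity to the model
margin is asserted to 1e−4). Features are ordered by mean |attribution|
with alphabetic tie-breaks, and the top 25 feed each model.

# Models and stacking

Nine submodels (Parts I/II/III × 12/24/36 months) and three direct Total
models are gradient-boosted (DART) classifiers. Each target follows the
same path: an internal 75/25 stratified split; explainer-based feature
selection on the inner training part; randomized hyperparameter search
over wide ranges (lambda, alpha, eta, gamma, rate_drop, skip_drop
log-uniform on [1e−8, 1]; subsample, colsample_bytree on [0.5, 1];
scale_pos_weight on [0.8, 1.2]; max_depth on 6–36; min_child_weight on
1–10; grow_policy, sample_type, normalize_type categorical), selected by
validation F1 at threshold 0.5; final refit on all labelled training
rows at the early-stopped round count. Configurations whose validation
predictions are single-class at the 0.5 threshold are rejected during
selection: under a log-uniform eta reaching 1e−8, such degenerate
all-one-class fits otherwise win on F1 at imbalanced prevalence while
carrying no discriminative content.

**Stacking.** For training rows, each submodel's probability is produced
out-of-fold (5-fold stratified refits), so no subject's meta-feature
comes from a model that saw that subject. The meta table is the nine
out-of-fold probabilities plus the baseline features selected for the
direct Total model at the same horizon; feature selection is applied
again at the meta level, so longer-horizon subpart predictions can (and
do) enter the final model. The meta classifier is the same boosted
family, but its randomized search is scored by pooled 5-fold
cross-validated ROC AUC rather than a single split: the meta table is
narrow, making this affordable, AUC is the meta layer's reported
headline metric, and single-split F1 selection was measurably unstable
at these sample sizes. For external cohorts, `predict()` averages the
five stacking fold models per submodel (matching the distribution the
meta-model was trained on); the full-training-cohort submodels are also
kept and can be selected with `submodel_predict = "full"` — the measured
difference is within a few thousandths of AUC.

Comparators (`comparator_models()`) are an unpenalized logistic
regression and a balanced random forest (per-class balanced bootstrap
per tree). Feature-class ablation (`ablate()`) removes every column of
one class and refits the entire pipeline from feature selection onward.
The classification threshold is 0.5 throughout; `n_trials` defaults to
25 — at desk scale this keeps a full stacked fit under a minute while
still sampling each categorical branch of the space several times.

# The synthetic paired cohorts

`generate_cohort()` draws, per subject: a latent progression subtype
(motor catch-up / non-motor catch-up / non-progressor), baseline subpart
severities whose subtype means encode the catch-up contrast (motor
catch-up subjects start ~5 points *lower* on Part III than
non-progressors, mirroring the observational pattern that progressors
are less impaired at baseline), and piecewise-linear latent trajectories
over 0–12, 12–24 and 24–36 months. The first-interval slope of each
subpart is the sum of

* a subtype mean (the catch-up structure),
* continuous couplings: −0.30 × own-subpart baseline (catch-up),
  +0.10 × non-target baselines, −0.50 × MoCA on Part I, −0.18 × SE-ADL
  on Part II, small age and monogenic effects,
* genetic effects acting through genotypes that are actually scored by
  the genetics module: −2.4 points/year/SD of PD polygenic risk on
  Part III (40% of that on Part II; protective) and +1.2 points/year/SD
  of the educational-attainment score on Part III,
* a shared transient factor plus subject noise.

In later intervals the *persistent* component (subtype + couplings +
genetics) carries forward at 0.35/0.30 strength while the transient
component mean-reverts at −0.45: initial progressors slow or reverse,
initial non-progressors drift upward, and cumulative slopes over longer
horizons are cleaner readouts of the underlying propensity — the
structural reason longer-horizon submodels are more robust and stacking
beats direct prediction. Visit-level Gaussian noise (SD 1.3/1.4/2.6 for
I/II/III) is added per visit; scores are clamped at zero, rounded, and
allocated to item columns by multinomial split (items are feature
columns, not psychometric objects). Treated subjects (Bernoulli,
independent of progression) have observed scores masked by −0.67, −1.5,
−3.67 — exactly what the offset estimator should recover.

Genotypes comprise the 90 + 763 scored variants (non-palindromic,
independent draws) plus 120 unscored variants in linkage blocks, with
planted QC failures (low call rate, monomorphic, gross HWE violation) so
QC and pruning have real work to do. The PPMI-like profile has 64%
12-month Total progressors, 25% treated, imaging available, 30%
monogenic carriers; the PDBP-like profile has 48% progressors, 75%
treated, no imaging, 9% carriers, an older/more-female mix, and sits
~3 Part-III points higher at baseline — a genuine covariate shift for
external validation. The subtype mix is derived from the prevalence
target with a 1.06 inflation compensating noise-induced label flips;
empirical prevalences land within ±0.02 of target at n = 2000, and
between-subpart Jaccard overlaps fall in 0.45–0.70 as in the real
cohorts.

Ground truth (subtype, latent slopes, standardized scores, the
designated strongest and null feature classes) lives in a side table
(`$truth`) written separately by `write_cohort()`; the analysis pipeline
never reads it. The physician-exam class is designated strongest because
the catch-up subtype structure is intrinsically exam-based; imaging
carries no planted signal and is the null class for ablation checks.

What the generator does **not** emulate: item-level psychometrics
(items are multinomial splits of the subpart sum), realistic LD beyond
block structure, CSF biomarkers, raw imaging, visit-window jitter, or
informative dropout. Passing tests therefore demonstrate that the
pipeline recovers planted structure under realistic noise, missingness
and cohort shift — not that it attains any particular accuracy on real
patient data.

# Trial enrichment

`required_sample_size()` is the pooled-variance two-proportion z-test
formula with 1:1 allocation, two-sided α = 0.05 and 80% power by
default, ceiling-rounded per arm before doubling. At a 50% control-arm
progression rate and a 10% relative risk reduction it returns 3130
participants — "just over 3000". `enrichment_gain()` re-runs the formula
with the control rate raised to the enriched progressor prevalence
(0.75) at the same relative risk reduction: 1142 participants, a ratio
of ~0.36. Note the formula makes enrichment *much* stronger than a
one-third drop — the absolute arm difference grows with the control
rate while the binomial variance shrinks; the package reports the
closed-form value and leaves the arithmetic to speak for itself. An
empirical check (100k simulated trials at the returned N) confirms the
nominal power within 1.5%.

# Numerical and protocol choices

* Endpoint matching window ±3 months; baseline is the visit nearest
  month 0.
* Slopes are annualized; only the sign matters for labels.
* Jaccard of two empty progressor sets is defined as 1 with a warning.
* Wilcoxon rank-sum comparisons use `stats::wilcox.test` (exact for
  small tie-free samples, normal approximation with continuity
  correction otherwise).
* PR AUC uses conservative step interpolation (no linear interpolation
  between PR points); ROC AUC is trapezoidal and is asserted equal to
  the Mann-Whitney normalization on random fixtures.
* Uncertainty is subject-level nonparametric bootstrap (percentile
  intervals); no interval construction is canonical for clinical
  prediction tables, so none is claimed as exact.
* Zero-variance columns are centered, not rescaled (scale forced to 1
  with a warning).
* A single global seed fans out to per-stage seeds via
  `stage_seed(seed, offset)` = `(seed*101 + offset) mod (2^31 − 1)`.
* Problem sizes in the test suite: cohorts of 600 (training) and 600
  (external) with 8 search trials for the stacking comparison; 600 with
  a 75/25 split and 4 trials for the ablation ordering; 2000 subjects ×
  10 seeds for planted-effect recovery. These sizes give stable medians
  across seeds while keeping a full run at desk scale.

# Known limitations

* The stacked pipeline's absolute AUC on the synthetic cohorts (~0.65
  external) is set by the generator's noise budget, not by the method;
  it is deliberately in the regime where model ranking, not ceiling
  performance, is informative.
* The tuning space is deliberately wide, including a log-uniform eta
  reaching 1e−8; most draws are therefore weak, and small `n_trials`
  leans on the degenerate-rejection rule above.
* Offsets, imputation values and scalers assume the external cohort's
  masking and measurement model matches the training cohort's.
* No genome-build liftover, no PCA against a real reference panel, no
  imputation of untyped variants; ancestry filtering consumes
  precomputed PC coordinates.
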
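---
title: "Organ-specific proteomic aging clocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-specific proteomic aging clocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

organclock implements a complete organ-resolved proteomic aging-clock
pipeline: mapping plasma proteins to organs from tissue expression, training
gradient-boosted age regressors with shadow-feature selection, sparsifying
them by SHAP-guided recursive feature elimination, deriving aging phenotypes,
and testing their associations with disease outcomes. This vignette explains
the models, the tunable parameters and the design choices; every empirical
claim here is recomputed by the package's tests or by
`scripts/acceptance.R`.

## The scientific problem

Biological age can diverge from chronological age, and it can do so
differently in different organ systems. Plasma proteomics offers a single,
minimally invasive readout of many organs at once: if a protein's encoding
gene is expressed predominantly in one organ, its plasma level is a
peripheral signal of that organ's state. A clock trained to predict
chronological age from such organ-enriched proteins yields, through its
errors, a measure of organ-specific aging: the **age gap**, the residual of
predicted ("proteomic") age regressed on chronological age. Subjects whose
organ age gap exceeds ±1.5 cohort standard deviations are called **extreme
ageotypes** (aged or youthful) for that organ.

## Organ-enrichment mapping

A gene is *organ-enriched* when its expression in one organ is at least
fourfold higher than in every other organ. Tissue-level expression is first
collapsed to organ level by taking, per gene, the **maximum over the organ's
tissue subtypes**; the fold rule is then applied to the collapsed matrix. A
second, independent expression resource is used for confirmation by applying
the same rule, and a protein is retained only when both resources assign the
same organ.

Conventions where the rule is silent:

* The boundary case (exactly fourfold) qualifies ("at least fourfold").
* A zero runner-up with positive top expression qualifies (the ratio is
  unbounded); the recorded fold is `Inf`.
* Genes absent from the confirmation resource are dropped by default
  (strict mode); `lenient = TRUE` keeps them unconfirmed.
* Ratios are computed on expression as-is: the fold test is invariant to any
  common rescaling of units, so no log transform is applied.
* The fold test is applied to organ-collapsed columns in both resources, for
  symmetry.

At most one organ can win a fourfold contest, so assignments are unique by
construction; this is asserted on every run.

## Cohort preprocessing

Protein values are log2-scale relative quantities with missingness allowed.
QC follows the usual plasma-panel conventions: proteins missing in strictly
more than 20% of subjects are dropped first, then subjects missing strictly
more than 50% of the retained proteins ("more than" is read as a strict
inequality, so the boundary fractions survive). Each retained protein is
rescaled to the unit interval and centred on its median, in that order; the
per-protein `(min, max, median)` triple is stored so an external cohort can
be projected either with frozen training parameters or with per-cohort
re-estimation (the default, since independently profiled cohorts are
normalised separately). Missing proteomic values are never imputed — the
tree learner routes them natively.

Decimal chronological age is the calendar-day count from an assigned birth
date (first day of the known birth month) to the visit date, divided by
365.25.

## The clock

Each clock is a gradient-boosted tree regressor of decimal age on a protein
panel, trained in five stages on a 7:3 train/test split:

1. **Hyperparameter search** — random search over learning rate
   (log-uniform on [0.03, 0.3]), tree depth (2–8), minimum child weight
   (1–20), row subsampling (0.6–1) and feature subsampling (0.3–1), each
   configuration scored by fivefold cross-validated R² with early stopping
   (cap 200 rounds, patience 10). The full-scale convention is 200 trials;
   the desk default used throughout the tests is 30 trials, which the
   simulations show is sufficient at a few thousand subjects.
2. **Boruta shadow-feature selection** — at each trial every surviving
   feature gets a shadow copy made by permuting its column; a model is fit
   on real + shadow features; features are scored by mean |SHAP| on the
   training data; and every real feature scoring below the *maximum* shadow
   importance (the 100% threshold) is removed. The procedure stops when a
   trial removes nothing (or at the trial cap, default 200). Removal is
   judged per trial, and the trial log records every removal so cumulative
   variants can be recomputed post hoc.
3. **Re-tuning** on the selected subset, same search.
4. **Final fit** on the training set, evaluated once on the held-out test
   set (reserved through tuning and selection).
5. **Out-of-fold prediction** — fivefold cross-validation over the full
   cohort with the final hyperparameters; each subject's proteomic age comes
   from the one model that never saw them. Fold assignment is simple random
   and seed-controlled (no stratification).

The learner is xgboost: gradient-boosted trees with native missing-value
split routing and exact per-sample SHAP attribution
(`predcontrib = TRUE`), so importance is the mean absolute SHAP value over
the training data. Where an attribution method is unavailable, permutation
importance (mean R² loss under column permutation) gives an equivalent
ranking; the test suite verifies the two agree on the top feature in ≥90%
of small seeded instances. Tree complexity is controlled by depth, which
plays the role of a leaf-count cap in depthwise growth.

External cohorts are scored by the mean of the fold models' predictions
(`project_clock()`), after preprocessing under the chosen scaling mode.

## Sparsification (RFE)

From the Boruta-selected panel, `rfe_shap()` repeatedly fits fivefold
cross-validated models, records the mean out-of-fold R² and mean |SHAP| per
protein (averaged over folds), and drops the least important protein until
one remains. Ties break toward the lexicographically smallest id and are
logged. Hyperparameters are held fixed along the path (re-tuning at every
size would be quadratic in cost; the risk is a mildly pessimistic tail of
the path). Importance is recomputed at every size rather than frozen from
the full model, because each elimination changes the attribution of the
survivors.

Panel choice replaces visual inspection of the R² curve with an explicit
rule: the smallest panel retaining at least a fraction (default 0.85) of
the full-panel R² — sparsified clocks of this kind are reported to retain
roughly 88% of performance — with a kneedle-style elbow detector available
as an alternative. Both the rule and its threshold are returned, so the
choice is auditable.

## Aging phenotypes

* **Age gap**: OLS residual of proteomic age on chronological age (with
  intercept). Residuals sum to zero and are uncorrelated with age by the
  normal equations; both identities are tested at machine precision. The
  slope/intercept are stored for frozen application to projected cohorts;
  per-cohort refitting is the default, mirroring the scaling choice.
* **Ageotypes**: aged above +1.5 cohort s.d. of the gap, youthful below
  −1.5. The s.d. comes from the same analysis sample as the gap regression
  and is frozen for external projection.
* **Burden groups**: counts of extremely aged (or youthful) organs mapped
  to 0, 1–2, 3–4, 5+.
* **Combined bins**: the mean of two z-scores, re-standardised (a
  sum-without-restandardisation mode exists), cut at ±0.5 and ±1.5 into
  five bins; intervals are left-closed so boundary values go to the upper
  bin.

## Association harness

Cox proportional-hazards models (Efron ties — the convention is otherwise
unstated) with the exposure standardised by its analysis-sample s.d., so
hazard ratios are per 1 s.d.; Wald intervals; a Schoenfeld-residual
diagnostic is available and the tests confirm it flags a simulated
time-varying effect. Logistic models report ORs per 1 s.d. Multiplicity is
controlled by Benjamini–Hochberg FDR within a user-declared family, with
non-converged (flagged) fits excluded from the family; the family
definition travels with the results. Relative contributions scale |z| of
the FDR-significant terms to sum to one; by default z-scores come from
separate per-organ models fitted within one family (a joint multi-organ
model can be assembled from the same primitives).

Transitions: MCI is a cognitive score at least 1.5 s.d. below the
education-stratum mean of baseline cognitively normal participants
(boundary inclusive); distress is a PHQ-4-like score ≥ 6. Multimorbidity is
two or more incident diseases within a category (and across categories
combined). Case–control matching draws up to five controls per case within
±2 years of age and the same sex, without replacement, seed-controlled.
Discrimination is compared by paired bootstrap of the AUC difference
(percentile two-sided p; 2,000 iterations by default), with resamples
lacking a class redrawn and counted. Cumulative incidence is one minus the
Kaplan–Meier survivor function per group.

## The synthetic cohort generator

No individual-level biobank data ship with the package; the generator
emulates the assumed data structure with recorded ground truth so every
stage is testable.

* **Ages** uniform on 37–70 years (the study-design baseline range); sex
  balanced; two continuous covariates.
* **Tissue expression**: each planted organ-enriched gene is expressed
  `planted_fold` = 8 above all other organs in both the discovery-like and
  confirmation-like matrix, each organ has two tissue subtypes, and
  multiplicative lognormal noise (σ = 0.2 by default) is drawn
  independently per matrix. An 8-fold plant against a 4-fold call threshold
  leaves realistic headroom for noise.
* **Proteome**: per organ, a latent aging offset ~ Normal(0, 3 years) per
  subject; an informative protein of organ *g* follows
  `intercept + slope × (age + offset_g)` with |slope| uniform on
  [0.02, 0.04] log2-units/year and random sign, residual noise 0.5 log2
  units; a 20% subset additionally gets a convex quadratic ramp beginning
  at age 55, emulating the accelerating late-life trajectories described
  for this class of markers (the exact functional form is a free choice).
  Background proteins are age-independent noise. Entries go missing
  completely at random (2% by default).
* **Outcomes**: exponential proportional hazards with linear predictor
  `Σ β_g × offset_g / sd(offset)` plus optional covariate effects,
  administratively censored at a 15-year horizon; the default baseline
  hazard (0.024/year) yields roughly 30% events. Default effects are
  ln(1.44) (mortality-like) and ln(1.88) (dementia-like) per 1 s.d. of the
  brain offset, the magnitudes reported for brain-age associations with
  mortality and dementia. Binary transition labels come from a logistic
  model with the same predictor.
* One RNG sub-stream per stage, derived from the master seed, so stages
  regenerate independently; identical configurations give byte-identical
  output.

The offset s.d. of 3 years is a working choice calibrated for test power —
the within-cohort variance of real organ age gaps is not publicly
documented — and the generator omits batch/plate structure, longitudinal
sampling, informative missingness and genotype effects. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
planted signal under clean assumptions, not performance on real cohorts.

## Problem sizes and numerical choices

The tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the recovery properties are comfortably
identifiable: clock recovery on 2,000 subjects with 200 candidate proteins
(20 informative) and 30 tuning trials; Boruta recovery on 1,000 subjects
with 5 signal + 45 noise proteins over 5 seeds; Cox recovery on 5,000
subjects over 20 seeds with a 500-replicate null calibration at n = 300;
AUC checks at n = 5,000 with 100 bootstrap-uniformity replicates at
n = 300; phenotype tail checks at n = 10,000.

Other numerical conventions: tuning R² is `1 − MSE/Var` on the validation
fold at the early-stopped best iteration, and the winning round count is
the rounded mean of per-fold best iterations; constant proteins are dropped
at scaling (their range is undefined); degenerate (constant-age) targets
are an error; empty Boruta survivor sets fall back to the candidate set
with a warning at the pipeline level, while `boruta_select()` itself
returns the empty set and lets the caller decide; single-configuration
searches return that configuration.

## Worked example

```{r example, eval = FALSE}
library(organclock)

cfg <- sim_config(n_subjects = 1000, organs = c("brain", "heart", "liver"),
                  n_proteins_per_organ = 8, n_background_proteins = 40,
                  seed = 1)
res <- run_pipeline(cfg, clock_search_space(n_trials = 10, k_folds = 5),
                    organs = c("organismal", "brain"))
res
glance(res$clocks$organismal)
autoplot(res$clocks$organismal)
autoplot(res$rfe$path, retention = 0.85)
res$associations
```

## Known limitations

* The generator's linear-plus-ramp trajectories and MCAR missingness are
  simpler than real plasma-proteome dynamics; transfer claims to real
  cohorts require real data.
* Hyperparameters are not re-tuned along the RFE path.
* Sex-specific clocks and alternative learners are out of scope, as are
  genetic analyses (GWAS/PRS), metabolite and imaging catalogs, and
  clinical-biomarker clocks.
* The FDR family boundary is the user's declaration; no cross-family
  hierarchy is imposed.
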
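---
title: "Evaluating prognostic models of transition to psychosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating prognostic models of transition to psychosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psytrans)
```

## The scientific question

Individuals meeting At-Risk Mental State (ARMS) criteria transition to a
first episode of psychosis at a rate far above the population baseline, yet
most never transition. A prognostic biomarker that separates the eventual
transitioners (ARMS-T) from the non-transitioners (ARMS-NT, defined by at
least two years of psychosis-free follow-up) at baseline would have obvious
clinical value. `psytrans` implements a complete, leakage-free evaluation
pipeline for that question across three baseline modalities — regional and
voxel-based structural MRI, genome-wide genotypes summarised as polygenic
and brain-eQTL scores, and environmental risk exposures — and, because
clinical cohorts of this kind cannot be shared, pairs the pipeline with a
seeded synthetic-cohort generator so that every stage is exercised and
calibrated without any private data.

The evaluation logic, in order:

1. **Matched balanced subsampling.** All ARMS-T subjects are kept; an
   equal-sized ARMS-NT group is drawn so the two groups are statistically
   indistinguishable on age (two-sided Mann–Whitney U, p > 0.05) and sex
   (two-sided Pearson chi-square, p > 0.05), with scan-protocol matching
   one-to-one for imaging data. The draw is repeated five times, giving
   five bootstrap replicates.
2. **Nested cross-validation.** Hyperparameters are tuned strictly in an
   inner 5-fold cycle; generalisation is estimated in the outer cycle under
   three schemes: leave-one-protocol-out (LSO), leave-one-pair-out (LPO,
   one ARMS-T plus one ARMS-NT of the same protocol per fold), and a
   stratified 5-fold.
3. **Per-fold feature preparation.** Regional volumes are divided by total
   intracranial volume (TIV); every feature is min-max scaled with
   training-fold statistics; voxel families are reduced by robust PCA
   (median/MAD standardisation, components up to 80% explained variance,
   capped at half the training size); regional families optionally pass a
   greedy forward selection keeping the top 10% of features.
4. **Classifiers.** A linear-kernel SVM (cost grid `2^l`, `l` in −5..4)
   for imaging features; elastic-net logistic regression (mixing 0–1 by
   0.1, penalty 0.01–1 by 0.01, via glmnet) for SNP, eQTL-score and
   exposure features; plain logistic regression with a 0.5 probability
   threshold for the single polygenic (PRS) and environmental (ERS) risk
   scores, in a simple LPO scheme without an inner cycle.
5. **Significance.** The out-of-fold balanced accuracy
   (BAC = (sensitivity + specificity)/2) is permutation-tested against the
   50% chance level: labels are permuted (stratified by protocol), the
   *entire* analysis — fold construction, preparation, tuning — is re-run
   per permutation, and the add-one p-value is reported. A configuration
   is significant when p < 0.05 in at least 3 of the 5 bootstrap
   replicates; only modalities with a significant configuration pass the
   gate to a multimodal model. A one-tailed exact Wilcoxon signed-rank test
   of the median BAC against 0.5 is available as an alternative summary.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws rosters with the study's demographic structure:
ages normal (mean 23, sd 4.5) truncated to 14–45, 55% male, three scan
protocols, and follow-up at least two years for ARMS-NT. The cohort shapes
used throughout (23 + 76 sMRI, 21 + 54 genetic, 37 + 97 environmental)
mirror the study sub-cohorts. Because the source tables report only
summaries, the exact distributions are this package's choice and are fixed
here once.

`generate_smri_features()` produces the five feature families at their
true regional dimensions (64 + 64 + 272) and a configurable voxel scale
(default 2,000 columns — the full voxel counts are a scale parameter, not a
structural property). Regional volumes are proportional to a subject's TIV
plus unit-variance noise, which is what makes TIV normalisation genuinely
denoising rather than decorative. A per-protocol additive offset (default
0.3 within-group SD) emulates scanner effects so the site-aware schemes are
meaningfully exercised. Informative features are separated by `cohens_d`
within-group SDs between groups.

`generate_genotypes()` draws binomial(2, MAF) dosages with uniform MAFs
and, under signal, shifts the effect-allele frequency in the ARMS-T group
so the dosage mean difference equals `cohens_d` dosage SDs, with weights
constrained positive for informative SNPs. `synthetic_eqtl_panel()` builds
a 141-gene brain panel shape. `generate_exposures()` draws the eight
exposure factors (tobacco, cannabis, migrant status, ethnic minority,
urbanicity, parental age, childhood trauma, season of birth) at plausible
base rates, exponentially tilted toward at-risk levels under signal, with
completely-at-random missingness.

Deliberately **not** emulated: image-level artefacts (no NIfTI volumes are
synthesised), linkage disequilibrium and imputation error, informative
missingness, site-by-group confounding, and ancestry structure. Passing
calibration on synthetic data therefore shows the *pipeline* is unbiased
and leak-free under the stated generative model; it cannot show that real
cohorts meet that model.

## Numerical and design choices

* **Matching algorithm.** The source design states the criteria, not the
  algorithm. Rejection sampling over protocol-stratified uniform draws is
  used because the acceptance criteria are then exact by construction;
  greedy nearest-age matching was rejected as it biases the age tails. The
  attempt budget defaults to 10,000; on matched generative marginals the
  median accepted attempt is 1–3.
* **Chi-square without continuity correction.** The sex comparisons in the
  cohort tables are reproduced only by the uncorrected Pearson statistic,
  so the uncorrected form is fixed, not configurable. Fisher's exact test
  uses the sum-of-smaller-probabilities two-sided rule for the same reason.
* **Linear SVM.** The solver is a dual coordinate-descent method for the
  L2-regularised hinge loss — the standard algorithm for linear SVMs at
  this scale — with the bias carried as a weakly regularised augmented
  column (scale 4) and a deterministic shuffle stream, so results are a
  pure function of data and seed. The engine solves the whole cost grid
  warm-started in ascending order. Convergence tolerance 0.05 on the
  projected gradient with at most 150 passes; the permutation loop uses a
  compiled batch path that replicates the R engine decision-for-decision
  (asserted by test). Agreement with an independent reference SVM
  implementation is checked in the test suite (decision-value correlation
  > 0.98 on signalled data); tiny discrepancies concentrate in degenerate
  near-zero-margin fits where solver conventions for the intercept differ.
* **Tie-breaking.** Inner-fold mean BAC ties are resolved deterministically:
  smallest cost for the SVM; largest penalty, then smallest mixing for the
  elastic net; candidate feature of lowest index in the forward search.
* **Forward selection reading.** The stepwise search ranks candidates by
  mean inner-fold BAC of a fixed-cost linear SVM and stops at
  `max(1, floor(0.1 p))` features. The alternative reading — keep only
  additions that improve accuracy, possibly stopping early — is noted but
  not implemented; the fixed-cardinality reading is the only one that
  yields the stated 10% feature count unconditionally.
* **Robust PCA.** Reference implementations of the cited robust PCA are
  not reproducible from the text; PCA on median/MAD-standardised features
  is used, with classic mean/SD PCA behind a flag. Zero-MAD features are
  dropped. The component cap `floor(n/2)` binds before the 80% variance
  target in every realistic inner fold of this design.
* **Unclamped min-max.** Test values outside the training range scale
  linearly outside [0, 1]; clamping would discard information the design
  never says to discard.
* **Degenerate folds.** Under label permutation at desk scale an inner
  training fold can lose a class; such folds carry no ranking information
  and are skipped by the tuners and the forward search, which error only
  when no usable fold remains. Outer training folds must always contain
  both classes.
* **Environmental score.** The ERS is additive in log relative risks under
  the stated factor-independence assumption, with missing factors
  contributing zero (the population-average contribution); the
  multiplicative relative-risk product is the same score exponentiated.
  Dosage files are assumed pre-oriented to the weight table's effect
  allele; orientation QC belongs upstream.
* **Permutation scope.** Each permutation re-runs the complete nested CV —
  including preparation and tuning. Permuting only test labels was
  rejected: it ignores training-phase optimism. The permutation scheme
  itself matters more than it may appear: keeping the fold structure fixed
  while permuting labels over the whole subsample is *anti-conservative*
  (measured at ~12% rejection at the nominal 5% level on null cohorts),
  because the observed folds are built from the true labels — every
  training partition is balanced — while permuted labels train unbalanced,
  which left-shifts the null BAC distribution. The calibrated scheme
  therefore permutes labels stratified by scan protocol and rebuilds the
  fold structure from the permuted labels with the same scheme and seed;
  observed and permuted statistics are then exchangeable under the null by
  construction (measured rejection ~2–3%, conservative only through the
  discreteness of BAC at 46 predictions). Protocol stratification also
  keeps the leave-one-pair-out parity requirement satisfiable for every
  permutation. The fixed-plan variant remains available (no `roster`
  argument) for comparison. The permutation count defaults to 1,000 and is
  configurable; the add-one formula keeps every p strictly positive.
* **Two stated significance rules.** The 3-of-5 permutation rule is the
  primary path; the Wilcoxon-on-median-BAC variant is provided as a
  reporting option (`wilcoxon_median_bac()`), since both appear in the
  source design.

## Calibration results the test suite computes

The acceptance tests (in `tests/testthat/test-acceptance.R`) verify, at
desk scale chosen to keep the suite within minutes on one CPU:

* the five printed demographic p-values (0.380, 0.411, 0.422, 1, 0.070)
  from their integer contingency tables, to three decimals;
* chance-level mean nested-CV BAC (within ±3 points of 50%) for the linear
  SVM over 50 null cohorts of 23 + 23 subjects with 64 regional features;
* 5% empirical rejection rate (±3 points) of the permutation test at
  α = 0.05 over 200 null single-score cohorts with 200 permutations each —
  the same quantity `scripts/acceptance.R` recomputes;
* recovery of a Cohen's d = 1.5 signal on 5 of 64 regions by the 3-of-5
  rule in at least 80% of 20 seeded repetitions (24 permutations per
  replicate at this scale);
* exhaustive brute-force oracle agreement for the chi-square, Fisher,
  Mann–Whitney, signed-rank and confusion-metric implementations, and the
  structural counts of the grids, fold systems and selection sizes.

## Known limitations

The pipeline evaluates one modality at a time; the multimodal stage is a
gate plus a reporting hook, matching a design in which no modality passed.
Probability calibration of the SVM decision values, nonlinear kernels,
propensity-based matching, LD-aware polygenic scoring and multiple-testing
correction across configurations are all out of scope. Replicate overlap
in the ARMS-NT pool across bootstrap replicates is permitted and recorded
in the subsample manifest; whether the original design allowed it is not
stated.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(families = c("ROIGM", "PRS"), schemes = "LPO",
                       n_replicates = 5, n_permutations = 199, seed = 1,
                       output_dir = "results")
res <- run_experiment_grid(cfg)
print(res)
```
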
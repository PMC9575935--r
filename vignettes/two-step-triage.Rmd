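---
title: "Two-step KD/FC triage: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step KD/FC triage: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
two-step triage model and its assumptions, the calibration machinery, the
synthetic cohort generator that stands in for patient data, and the design
choices made where the method description left matters genuinely open.

## The clinical setting and the abstaining classifier

A child suspected of Kawasaki disease (KD) presents with fever and some
subset of five principal signs; the differential is against a broad class of
febrile controls (FC) — children with unexplained fever, at least one
principal sign, and some other final diagnosis. Because the cost of a missed
KD (untreated coronary vasculitis) and of a false KD call (unnecessary IVIG)
are both high, the classifier is designed to abstain: every patient receives
exactly one of the calls KD, FC or INDETERMINATE, and the indeterminate
group is understood to need further clinical work-up rather than an
algorithmic verdict.

## Step 1: Fisher discriminant with PPV/NPV-calibrated dual thresholds

The step-1 score is linear, `s(x) = w'x + b`, over illness days, the five
criteria encoded 0/1, and a laboratory panel (default: the nine analytes of
the `"taiwan"` profile — WBC, %eosinophils, hemoglobin, %monocytes,
%lymphocytes, %neutrophils, platelets, CRP, ALT; bands, GGT and ESR are kept
in the schema but excluded from the default model because they are not
routinely collected at the originating centre, and can be re-enabled with
`kd_features("full")`). The direction solves the two-class Fisher system
with pooled within-class covariance. Assumptions worth stating: the model is
linear in the raw features (no transformations — illness days enter as
integers, criteria as indicators), and class covariances are pooled, which
is the classical LDA compromise rather than a claim about the data.

Numerical choices:

- **Ridge.** `lambda = 1e-6 * trace(Sw)/p` is added to the pooled
  covariance. The binary criteria can be nearly constant within a training
  cohort (e.g. conjunctival injection among 4-5-criteria KD), driving `Sw`
  toward singularity; the ridge is small enough to be irrelevant when `Sw`
  is well conditioned.
- **Orientation.** The sign of `w` is normalized so the mean KD score
  exceeds the mean FC score; the intercept centres the score midway between
  the class means. Neither affects calls, both make scores comparable
  across fits.
- **Candidate cuts.** Threshold calibration scans midpoints between
  adjacent sorted unique scores plus the two infinities — a finite,
  exhaustive, reproducible candidate set. `tau_kd` is the smallest cut
  whose induced KD calls meet the PPV target (thereby calling as many
  patients KD as the constraint allows); `tau_fc` mirrors it for NPV.
- **Overlap collapse.** With strongly separated classes the PPV-feasible
  and NPV-feasible zones can overlap (`tau_kd < tau_fc`). Both thresholds
  are then set to the midpoint of the overlap, giving an empty
  indeterminate zone; both achieved predictive values are reported and can
  dip slightly below target in this regime. The alternative (keeping a
  nonempty zone by force) would abstain on patients both rules agree about,
  which we judged indefensible.
- **Boundaries.** Both thresholds are closed and the KD comparison is made
  first, so ties at a threshold are deterministic.
- **Targets.** The description of the original algorithm reads "PPV or
  NPV of 95%"; this implementation targets *both*, each on its own
  threshold, because each threshold controls exactly one predictive value.
  Targets are parameters (`target_ppv`, `target_npv`, default 0.95 each).

Calibration fails loudly (condition class `kd_calibration_error`, reporting
the best achievable value) rather than silently returning an extreme cut
when a target is unattainable — e.g. when the top-scoring calibration
patient is an FC.

## Missing laboratory values: kNN imputation

Laboratory values are imputed with k nearest neighbours (default `k = 5`, a
conventional choice exposed in configuration; the method description states
only that a kNN algorithm was used). Design:

- **Robust standardization.** Features are centred at the median and scaled
  by the IQR (unit scale for constant features) because the lab analytes
  are right-skewed; mean/SD standardization would let CRP or ALT outliers
  dominate the metric.
- **Missingness-aware distance.** The distance between two records is the
  Euclidean distance over the standardized features *observed in both*,
  divided by the number of shared features, so records with different
  missingness patterns remain comparable. A record sharing no observed
  feature with any reference row falls back to reference medians with a
  warning.
- **Donor pools per analyte.** The k nearest neighbours are taken among
  reference rows in which the target analyte is observed, and the imputed
  value is their unweighted mean; distance ties break by ascending
  reference index for reproducibility.
- **Scope.** Only laboratory analytes are imputed; the criteria and illness
  days are mandatory fields. The imputer draws donors strictly from the
  cohort it was fitted on (the training set), never from the query cohort —
  whether the original work pooled train and test for imputation is
  unstated, and the strict choice is the one that keeps evaluation honest.

Imputation is idempotent, never rewrites observed values, and imputed
values lie within the range of their donors.

## Step 2: criteria-count-stratified forests

Step-1 indeterminates are routed by their criteria count into four strata —
≤2, 3, 4, 5. The stratification into "four sub-cohorts by number of
criteria" is part of the method; the exact bin boundaries are not stated,
and were chosen as the only four-bin partition consistent with the reported
result breakdowns (which repeatedly cut at ≤2 / 3 / ≥4); they are
configurable. Each stratum's forest:

- trains on the **full stratum** of the training cohort, not only on its
  step-1 indeterminates — the indeterminate subsets are far too small to
  train on (a documented assumption, as the original choice is unstated);
- uses 500 trees, unlimited depth and sqrt-feature subsampling under a
  fixed per-stratum seed (hyperparameters unstated in the method
  description; these are the `randomForest` conventions);
- thresholds its out-of-bag KD vote fraction with the same PPV/NPV
  calibration as step 1 — OOB votes keep the calibration honest — falling
  back to a single 0.5 cut (no stratum-level abstention) when the stratum
  calibration is infeasible;
- degrades to a flagged majority-prior stub when the stratum has fewer
  than 10 training records in either class.

Step 2 only ever changes INDETERMINATE calls; confident step-1 calls are
immutable, so the cascade can be audited stage by stage
(`ClassificationResult` rows carry call, stage, score and stratum).

## Evaluation conventions

The three-way confusion table is 2 (truth) x 3 (call). Sensitivity and
specificity keep indeterminates in the denominator; PPV and NPV exclude
them. These conventions make
`sensitivity + indeterminate rate + misclassification rate = 100%` an exact
identity per class (kept in rational form internally; percentages are
rendered to one decimal with round-half-even). Zero-denominator metrics are
`NA` and serialize as `null`, never 0.

`fisher_exact` follows the two-sided minimum-likelihood convention (summing
hypergeometric probabilities of all tables at most as probable as the
observed one, relative tolerance 1e-7). Other conventions — tail doubling,
or chi-square approximations — can differ noticeably on moderate tables, so
the convention is recorded in the output. `mann_whitney_u` uses midranks,
an exact enumeration p-value when `n <= 20` without ties, and otherwise a
normal approximation with tie and continuity corrections, recording which
branch ran.

## The synthetic cohort generator

No patient-level dataset accompanies the study this package re-implements,
so the generator is the package's test bed. It emulates the published
*structure* of the cohort:

- **Criteria.** A criteria-count stratum (≤2 / 3 / ≥4) is drawn per patient
  from the published stratum occupancy (14/36/368 of 418 KD; 158/59/42 of
  259 FC), then the five signs are drawn jointly from an
  independent-Bernoulli model restricted to the stratum's counts. The
  Bernoulli parameters are *calibrated* (a fixed point over the 32 sign
  patterns, computed at spec construction) so that the conditional sign
  frequencies given the stratum match the published per-stratum table. A
  naive mixture with the published frequencies used directly as Bernoulli
  parameters would miss the conditional targets by over a percentage point
  in the large strata, because conditioning on the count shifts the
  marginals; calibration removes that bias exactly wherever it is feasible.
  One stratum is provably infeasible to match exactly: the published
  KD ≤2 frequencies average exactly two signs per patient, which would
  require the conditional count distribution to be degenerate at 2; the
  fixed point lands within 5e-4, far below sampling noise at that stratum's
  size. FC patients are never generated with zero criteria (an FC has at
  least one sign by definition).
- **Missingness.** Missing-completely-at-random per analyte (the published
  account gives rates, not a mechanism), with per-analyte rates
  concentrated in bands/GGT/ESR (not routinely collected) and rescaled in
  closed form so the fraction of records with at least one missing analyte
  is 54.3% (KD) and 98.8% (FC). Values are drawn first and masked last, so
  masking is a projection: switching missingness off changes nothing else.
- **Laboratories.** Log-normal (or zero-truncated normal) per analyte and
  group, clamped to the physiologic validity ranges. **The published study
  reports no laboratory summary statistics**, so the locations and scales —
  e.g. CRP medians 80 vs 30 mg/L, WBC 13.5 vs 10 x10³/µL, ALT 45 vs 20 U/L
  — are synthetic stand-ins chosen once to be clinically plausible, and are
  labelled as such. This is the main respect in which passing tests do not
  certify real-data behaviour: the true KD/FC laboratory overlap is almost
  certainly larger than the default spec's, so real-world indeterminate
  rates and misclassification rates will be worse than synthetic ones.
  Demographics (median ages 1.3 vs 1.0 years, 37.6% KD infants, male
  fractions 60.5%/53.3%) and illness-day distributions (KD median 5 days
  with 21.8% at 8–10; FC median 2 days with 2.7% at 8–10) follow the
  published marginals.
- **Not emulated.** Correlations among analytes, criteria–laboratory
  coupling (available as an option, off by default), seasonal or site
  effects, coronary trajectories, and any real patient.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`with_seed` leaves the
caller's RNG state untouched). The test suite exercises distributional
properties at 10,000 records per group and the full pipeline at 1,000 per
group over five independent train/test seed pairs — sizes chosen to put
3-standard-error binomial bands well below the effects being checked while
keeping the suite quick to run; the acceptance script uses the same
pipeline sizes.

## Known limitations

- The original discriminant and forest coefficients were never published;
  this package re-trains the architecture rather than reproducing the 2016
  US model's numbers, and the published Taiwan performance figures are
  reproduced from the printed count tables through the evaluation module,
  not from patient data.
- Under the default synthetic separation the 95%/95% feasible zones
  usually overlap, collapsing the indeterminate zone; stricter targets
  (e.g. 99%/99%) or harder synthetic overlap exercise the cascade.
- Percent rendering in the source tables mixes conventions (one count is
  printed as both 4.7% and 3.5%; one rate as 98.0% where the counts give
  98.1%); wherever counts and percentages disagree, the counts are taken
  as authoritative and comparisons are made on exact rationals.
- Three of the fifteen published sign-table p-values match an uncorrected
  chi-square rather than the minimum-likelihood Fisher convention; the
  acceptance test reports these as convention-dependent deviations.
- Single imputation only: imputation uncertainty is not propagated into
  the calls.
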
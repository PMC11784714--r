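---
title: "Methods: staging cognitive impairment with cogstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging cognitive impairment with cogstage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Alzheimer's disease progresses through recognisable cognitive states —
cognitively normal (CN), subjective memory concern (SMC), early and late
mild cognitive impairment (EMCI, LMCI), and dementia (AD) — and
neuropsychological assessments (ADAS-Cog, MMSE, CDR sum of boxes, RAVLT,
logical-memory recall, trail making, FAQ) shift systematically along that
continuum. cogstage implements a binary-classification pipeline over pairs
of these states: which small battery of assessments best separates each
pair, and how well does a classifier ensemble built on that battery
perform?

The pipeline has six stages: cohort ingestion; inclusion-criteria filtering
and nominal encoding; separation into thirteen pairwise comparison
datasets; synthetic augmentation for class balance; feature selection; and
cross-validated evaluation.

# Cohort filtering and encoding

Input is a per-visit tabular export in the ADNIMERGE dialect. The inclusion
criteria are applied in a fixed order, because the intermediate row counts
are part of the analysis record:

1. drop rows with a missing visit code (then drop the `VISCODE` column);
2. keep enrolment ages in the **closed** interval [53, 95] years;
3. keep subjects whose ethnicity field matches the Hispanic/Latino
   category (then drop `PTETHCAT`);
4. prune all remaining columns except the fourteen retained features
   (`AGE`, `PTGENDER`, `PTMARRY` and eleven assessment scores) and the
   diagnosis `DX.bl`.

Nominal variables are encoded as CN = 0, SMC = 1, EMCI = 2, LMCI = 3,
AD = 4; Female = 0, Male = 1; Never married = 0, Married = 1, Divorced = 2,
Widowed = 3. Rows containing any missing value are then removed
(complete-case analysis — no imputation). Every step's removal count is
recorded in an inclusion report.

Two filtering choices deserve a note. The ethnicity match defaults to the
anchored, case-insensitive pattern `^Hisp`: the ADNIMERGE convention writes
the *non*-Hispanic category as `"Not Hisp/Latino"`, so an unanchored
substring match on "Hisp" would retain exactly the rows the criterion is
meant to exclude. The pattern is configurable for other dialects. Second,
the empty string, `NA` and `N/A` are treated as missing markers, but the
code `-4` is not: ADNI uses it as a meaningful code in some columns, and
silently discarding those rows would be a data-loss bug. Both options live
in `cohort_config()`.

Visit handling is deliberately minimal: rows with a non-missing visit code
are retained and no per-subject deduplication is attempted, since the
filtering contract is defined row-wise. Longitudinal modelling of repeat
visits is out of scope.

# Thirteen pairwise comparisons

Phase 1 takes the ten unordered pairs of {CN, SMC, EMCI, LMCI, AD}. Phase 2
regroups CN+SMC into CN and EMCI+LMCI into MCI (AD unchanged) and takes the
three pairs of {CN, MCI, AD}. The phase-2 CN-vs-AD dataset is distinct from
the phase-1 one — its CN class also contains former SMC subjects — and both
are kept.

Within each comparison the group listed second (the more impaired state) is
class 1, so *sensitivity* always means detection of the more impaired
state. The source never states a polarity; this choice makes the metric
tables clinically coherent.

# Synthetic augmentation

Most comparisons are imbalanced (the AD group is by far the smallest).
Each comparison dataset gets a balanced "synthetic" counterpart built by
boosting-guided augmentation:

1. fit an adaptive-boosting ensemble of decision stumps (50 rounds by
   default) on the comparison dataset;
2. within each class, sample source rows with probability proportional to
   their final boosting sample weight — synthesis therefore concentrates on
   the regions the stump ensemble finds hardest to classify, widening the
   variation the synthetic data covers rather than replaying the class
   centre;
3. jitter every feature of a sampled row with zero-mean Gaussian noise
   whose SD is `perturbation_scale` (default 0.1) times that class's
   feature SD, clipped to the class's observed [min, max];
4. append the synthetic rows (with their source row's label) to the
   originals until both classes reach the majority count.

Original rows are never modified, no new label values can appear, and the
whole procedure is reproducible from a mandatory seed. One known
limitation: encoded nominal features (gender, marital status) are jittered
on their numeric scale like any other column, so synthetic rows can carry
fractional category codes. Range clipping keeps them in the valid interval,
and the downstream classifiers treat all features as numeric, but the
synthetic rows are not guaranteed to be categorically well-formed.

Boosting is a classification technique, not a generative model, so using
it for augmentation requires an interpretation. The one above — final
sample weights as a within-class sampling distribution plus SD-scaled
jitter — is the minimal mechanism that involves the boosting ensemble,
balances the classes, and broadens coverage of the hard regions. It is
isolated behind `augmentation_config()` so an alternative mechanism can be
swapped in without touching the rest of the pipeline.

# Feature selection

## Recursive elimination with a joint AIC/accuracy stop

Each iteration scores the current feature set twice:

* **AIC** = 2k − 2 ln(L), with L the maximized likelihood of a binomial
  logistic regression on the current features and k the coefficient count
  (features + intercept). The ensemble itself has no single likelihood, and
  logistic regression is its only probabilistic member, so its likelihood
  is the natural information-criterion proxy for the feature set.
* **accuracy**: the hard-voting ensemble's pooled accuracy under
  stratified 10-fold cross-validation on the same features.

Feature importance is the absolute standardized logistic coefficient
(features scaled to zero mean and unit SD before fitting), which keeps the
elimination criterion coherent with the AIC model; zero-variance and
aliased (collinear) columns score 0, and ties break toward the earlier
column. The least important feature is eliminated — exactly one per
iteration, for a deterministic trace — and the loop stops when the
candidate set after elimination is worse than the incumbent on *both*
criteria (higher AIC and lower accuracy), or when one feature remains. No
target number of features is prescribed anywhere.

The accepted set is the visited set with minimal AIC among those attaining
the best accuracy seen, preferring smaller sets on AIC ties: accuracy picks
the highest-performing sets, AIC the most parsimonious of them.

Whether the per-iteration accuracy should be the ensemble's or a single
member's is an open design point; the ensemble's cross-validated accuracy
is used because it is the quantity the pipeline ultimately reports, and the
member configurations are injectable if a cheaper proxy is wanted.

## Perfect separation

Several pairs (CN vs AD most prominently) are perfectly separable, where
the logistic maximum-likelihood estimate diverges. The fit is then
stabilized with a tiny L2 penalty (λ = 1e−8 on standardized features,
intercept unpenalized) solved by damped Newton iterations, the unpenalized
log-likelihood is evaluated at the stabilized coefficients, and the result
carries a `separated` flag. AIC stays finite (approaching 2k from above as
the likelihood approaches 1), which is exactly the behaviour the stopping
rule needs.

## The custom subset

The set selected on the *synthetic* dataset becomes the candidate set for a
"custom" model: every non-empty subset is enumerated, each subset's AIC is
computed on the *original* data, and the AIC-minimal subset wins (ties to
the smaller, then lexicographically earlier subset). Enumeration is refused
above 12 candidates — 2^12 logistic fits is the declared combinatorial
guard — with a greedy backward-elimination mode as the explicit escape
hatch.

# The ensemble

Five members, combined by unweighted majority vote (five binary voters
cannot tie):

| member | form | defaults |
|---|---|---|
| LR | L2-regularized logistic regression | λ = 1 on standardized features |
| ANN | single-hidden-layer perceptron (`nnet`) | 16 logistic units, ≤ 2000 iterations |
| SVM | RBF-kernel support vector machine (`e1071`) | cost 1, γ = 1/p |
| KNN | K-nearest neighbours (`class`) | K = 5 (odd, to avoid vote ties), Euclidean |
| NEARCENT | nearest centroid | per-class Euclidean centroids |

None of these hyperparameters is prescribed by the study design; the
defaults are conventional small-tabular-data settings, declared once here,
and every one is overridable through `member_config()`.

Features are standardized using the training rows only; the centring and
scaling travel with the fitted model, so held-out rows never influence the
fit (no leakage). Folds are stratified by class — the imbalanced AD groups
make plain k-fold assignment risky — with a non-stratified option (needed
e.g. for leave-one-out). Fold sizes differ by at most one, overall and
within each class.

Cross-validated metrics are computed two ways: from the pooled out-of-fold
confusion counts (primary, always defined when n > 0) and as the mean of
per-fold metrics (secondary, matching the "average the fold results"
reading). Both are reported, because published four-decimal tables do not
reveal which aggregation produced them.

# Metrics

Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
accuracy (TP+TN)/n, and F1 = 2·precision·sensitivity /
(precision+sensitivity), with class 1 the more impaired state. A zero
denominator yields an undefined value rendered `NA`; precision with TP = 0
but FP > 0 is a defined 0. F1 is undefined whenever precision or
sensitivity is undefined or both are 0 — a deliberate choice: a harmonic
mean of an undefined quantity is reported as undefined rather than coerced
to 0, even though software that silences zero-division warnings would print
0 there. Reports render to four decimal places in the Orig/Syn/Custom
layout of the study tables.

# The synthetic cohort generator

The clinical source table is access-controlled, so the package ships a
generator (`fixture_spec()` / `generate_fixture()`) instead of data. Its
defaults are the analysis conditions:

* five diagnosis groups (CN 136, SMC 94, EMCI 152, LMCI 132, AD 38)
  totalling 552 in-criteria rows, sized so that complete-case filtering
  leaves roughly 323 subjects with about 22 in the AD group — the scale of
  the study cohort;
* per-group assessment means and SDs at clinically realistic values,
  worsening monotonically from CN to AD, clipped to each instrument's range
  (MMSE 0–30, ADAS-Cog 11 0–70, ADAS-Cog 13 0–85, and so on). The FAQ
  distributions of CN and AD are far enough apart that FAQ alone separates
  the two groups cleanly — reproducing the headline behaviour of the study
  cohort, where a single functional-activities score carried the CN/AD
  distinction;
* a per-cell missing rate of 0.048 on the assessment columns, calibrated
  so complete-case attrition matches the study's 552 → 323;
* demographics: age uniform on [53, 95], gender and marital status uniform
  over their category sets, ethnicity Hispanic/Latino, visit code `bl`;
* optional contaminating rows, each violating exactly one inclusion
  criterion (25 missing visit codes, 50 out-of-range ages, 400
  non-Hispanic rows), so the ordered filter is exercised end to end.

What the generator does *not* emulate: correlations between assessments
within a subject (features are drawn independently given the diagnosis),
longitudinal structure, informative missingness, instrument floor/ceiling
pile-ups beyond simple clipping, and demographic association with
diagnosis. Pipeline results on fixtures therefore demonstrate that the
machinery is correct and that effect sizes of the assumed magnitude are
recoverable — not that the published per-comparison metric values
generalise, which would require the restricted cohort.

# Numerical choices and degenerate inputs

* AIC identity `aic = 2k − 2·log_likelihood` holds exactly by
  construction on every result object.
* Log-likelihoods use a softplus formulation safe at extreme linear
  predictors; Newton steps are halved until they ascend.
* Zero-variance features standardize to all-zero columns (unit divisor)
  and score zero importance; exact duplicates are aliased to zero by the
  ML fit.
* Empty classes and classes smaller than the fold count are reported as
  explicit skips or errors, never silently rebalanced.
* A single-row class with zero jitter warns that augmentation degenerates
  to duplication.
* Nearest-centroid distance ties go to class 0; KNN uses an odd K so its
  own vote cannot tie.

# Problem sizes

The test-suite and acceptance computations run at deliberately modest
sizes: the study-condition cohort (~1,000 raw rows, ~320 complete cases),
permutation-null checks at n = 200 over 50 seeds, feature-recovery checks
on six-feature fixtures (two informative at a 2-pooled-SD gap) over 20
seeds, and property checks on blob fixtures of 20–120 rows. These sizes
were chosen to estimate each property with comfortable Monte Carlo margins
while keeping a full run in minutes on one core.

# Limitations

* The augmentation mechanism is a declared interpretation of
  boosting-guided synthesis; other readings (e.g. boosting a generative
  learner, or SMOTE-style interpolation) would produce different synthetic
  sets. The interface isolates the choice.
* AIC is computed from the logistic proxy, not from the ensemble itself;
  an ensemble-wide information criterion is not well defined.
* All reported numbers in this repository come from synthetic cohorts;
  applying the pipeline to the restricted clinical export requires access
  to it (the reader function and criteria are dialect-compatible).
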
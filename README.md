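# cogstage

Staging cognitive impairment from neuropsychological assessments.

`cogstage` is an R package plus analysis workflow for binary
classification between stages of cognitive decline — cognitively normal
(CN), subjective memory concern (SMC), early/late mild cognitive
impairment (EMCI/LMCI, pooled as MCI), and Alzheimer's disease (AD) —
using only tabular neuropsychological assessment scores (ADAS-Cog 11/13
and its memory item, MMSE, CDR sum of boxes, the RAVLT subscores,
delayed logical-memory recall, trail-making time, FAQ) together with age,
gender and marital status. It is aimed at researchers who want an
auditable, fully seeded re-implementation of this kind of staging
analysis, and who may not have access to the restricted clinical export it
was designed around: a synthetic cohort generator reproduces the input
schema and study conditions, so every stage is runnable and testable out
of the box.

## What it computes

The pipeline runs six stages over an ADNIMERGE-dialect cohort table:

1. **Ingestion** — CSV reading with missing-marker normalization and
   column aliases (`read_cohort`).
2. **Filtering & encoding** — ordered inclusion criteria (non-missing
   visit code; age in [53, 95]; Hispanic/Latino ethnicity; column
   pruning), nominal encoding (CN = 0 … AD = 4; Female = 0, Male = 1;
   Never married = 0 … Widowed = 3), complete-case removal, with a
   per-criterion drop report (`apply_inclusion_criteria`,
   `encode_and_complete`).
3. **Comparison building** — the 13 pairwise datasets: all 10 phase-1
   pairs over {CN, SMC, EMCI, LMCI, AD} and 3 phase-2 pairs after
   regrouping CN+SMC→CN, EMCI+LMCI→MCI (`enumerate_comparisons`,
   `build_comparison`). The more-impaired group is class 1.
4. **Augmentation** — a balanced synthetic counterpart of each dataset,
   built by sampling rows with probability proportional to the final
   sample weights of an adaptive-boosting stump ensemble and jittering
   them inside each class's observed range (`augment_adaboost`).
5. **Feature selection** — recursive feature elimination whose stopping
   rule jointly tracks the Akaike information criterion,

       AIC = 2k − 2 ln(L),

   of a logistic model on the current feature set (k = features +
   intercept, L the maximized binomial likelihood) and the
   cross-validated accuracy of the classifier ensemble; the accepted set
   is the AIC-minimal set among those attaining the best accuracy seen
   (`select_rfe_aic`). A "custom" model then exhaustively enumerates
   subsets of the synthetic-selected set and keeps the AIC argmin on the
   original data (`refine_custom_subset`).
6. **Evaluation** — a five-member hard-voting ensemble (logistic
   regression, single-hidden-layer perceptron, RBF SVM, K-nearest
   neighbours, nearest centroid) under stratified 10-fold
   cross-validation, scored by sensitivity, specificity, precision,
   accuracy and F1 with explicit undefined-value semantics (zero
   denominator → NA; TP = 0 with FP > 0 → precision 0)
   (`fit_ensemble`, `predict_vote`, `cross_validate`, `compute_metrics`).

## Worked example

```r
library(cogstage)

# Synthetic cohort under the study conditions (no restricted data needed)
raw <- generate_fixture(fixture_spec(seed = 42))
fl  <- apply_inclusion_criteria(raw)
enc <- encode_and_complete(fl$cohort, fl$report)
enc$report$per_criterion_drops
#>       viscode           age     ethnicity complete_case
#>            25            50           400           246
enc$cohort
#> <cohort_table> 306 subjects x 14 features
#>   CN  SMC EMCI LMCI   AD
#>   70   49   85   78   24

# CN vs AD: select features, then cross-validate the voting ensemble
d  <- build_comparison(enc$cohort, comparison_spec(1, "CN", "AD"))
tr <- select_rfe_aic(d, cv_folds = 10, seed = 7)
tr
#> <feature_selection_trace> 14 iterations, stop: singleton
#> accepted: FAQ
cv <- cross_validate(subset_features(d, tr$accepted_set), k = 10, seed = 7)
cv$report
#> <metric_report> (pooled) sens=1.0000 spec=1.0000 prec=1.0000 acc=1.0000 f1=1.0000
```

Reading the output: the raw cohort of 1,027 rows loses 25 rows to missing
visit codes, 50 to the age window, 400 to the ethnicity criterion and 246
to complete-case removal, leaving 306 encoded subjects. For the CN-vs-AD
pair, elimination runs all the way down and accepts the single feature
FAQ (the functional-activities score), which separates the two groups
perfectly: all five pooled cross-validated metrics equal 1.0000 —
sensitivity here meaning detection of the AD class.

The full 13-comparison analysis is scripted under `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R   # raw synthetic cohort -> results/
Rscript analysis/02_filter_encode.R     # criteria, encoding, summaries
Rscript analysis/03_run_pipeline.R      # selection + evaluation, manifest
Rscript analysis/04_report.R            # metric tables (Orig/Syn/Custom)
```

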
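# recurtma

Predicting **early breast cancer recurrence** (return of the primary tumor
within three years of diagnosis) from H&E-stained tissue-microarray (TMA)
core images, in the setting of the Carolina Breast Cancer Study (CBCS): a
diverse, population-based cohort in which roughly 7% of patients experience
an early recurrence and each patient contributes 2–4 one-millimeter tumor
cores.

The package is aimed at analysts who want to reproduce, stress-test or
extend this style of histology-based risk stratification. Because the real
cohort data are restricted, a first-class synthetic study generator —
calibrated to the cohort's published statistical structure — makes every
stage of the pipeline runnable and testable end to end.

## The method

1. **Feature extraction.** Each core image is standardized per color
   channel to mean 0, SD 1, pushed through a convolutional feature
   extractor (a pluggable contract; the tested reference is a small
   deterministic fixed-seed stack, and a pretrained backbone adapter can
   satisfy the same interface), and the chosen layer's `C × h × w` feature
   map is spatially mean-pooled into one length-`C` vector per core
   (`C = 512` for a VGG16-class backbone). The extraction layer is chosen
   by a 90/10 grid search using the downstream classifier.
2. **Patient aggregation and classification.** A patient's core vectors
   are averaged into a single feature vector, and a soft-margin linear SVM
   is fit on a balanced, 1:1 age-matched (5-year bins) case-control set:
   minimize `½‖w‖² + C Σᵢ max(0, 1 − yᵢ(w·xᵢ + b))`, predicting recurrence
   by `sign(w·x + b)`.
3. **Two validation designs.** *Cross-patient*: label-stratified 10-fold
   cross-validation over patients (no patient in both train and test).
   *Within-patient*: train on half of each patient's cores, test on the
   other half — an intentionally optimistic design probing tumor
   "individuality" (within-patient cosine similarity of features ≈ 0.91 vs
   ≈ 0.84 between patients).
4. **Statistics.** Accuracy, sensitivity and specificity with
   normal-approximation binomial CIs `p̂ ± z√(p̂(1−p̂)/n)`; Kaplan–Meier
   cumulative incidence and Cox proportional-hazards HRs (Breslow ties)
   for image class vs time to recurrence; and relative frequency
   differences (RFD, identity-link binomial GLM) between image classes and
   genomic risk-of-recurrence categories (OncotypeDX, ROR-PT).

## Worked example

Published matched-sample counts are bundled; the comparator-marker rules
(grade 3 vs 1–2, ER-negative vs positive) reproduce the reported rows:

```r
library(recurtma)
mk <- reference_marker_counts()
summarize_confusion(mk$grade)$accuracy
#> 65.8% (95% CI: 59.3, 72.4), n = 202
summarize_confusion(mk$grade)$sensitivity
#> 73.3% (95% CI: 64.6, 81.9), n = 101

reference_tables()$rfd
#>            panel  rfd lower upper published_rfd matches_published
#>   cross_oncotype 13.8   7.4  20.1          13.8              TRUE
#>      cross_rorpt 21.5  14.3  28.6          21.5              TRUE
#>  within_oncotype 11.3   5.0  17.7          11.3              TRUE
#>     within_rorpt 17.4  10.1  24.6          17.4              TRUE
```

A full synthetic study — generate a 202-patient balanced cohort with
calibrated feature structure, run both validation schemes, the comparator
markers, survival and genomic association:

```r
cfg <- study_config(
  params = synthetic_params(n_patients = 202, balanced = TRUE, seed = 1),
  output_dir = "demo_run", seed = 1
)
rep <- run_study(cfg)
rep$metrics[, c("predictor", "accuracy", "accuracy_lo", "accuracy_hi")]
#>       predictor accuracy accuracy_lo accuracy_hi
#>           grade     65.3        58.8        71.9
#>              er     66.3        59.8        72.9
#>  within_patient     84.7        79.7        89.6
#>   cross_patient     63.9        57.2        70.5
```

Cross-patient accuracy lands in the low 60s (the regime reported for the
real cohort) while the within-patient design is, by construction,
optimistic. The run directory holds `predictions.tsv`, `metrics.tsv`,
`km.tsv` and `report.json`, all stamped with the configuration hash.

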
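# milsurv

Weakly supervised survival prediction from whole-slide-image tile features,
fused with a clinical Cox model — a reusable implementation of the combined
histologic + clinical prognostic analysis used for post-surgical
hepatocellular carcinoma (HCC), with a synthetic-cohort generator so every
stage runs and is tested without any restricted patient data.

## Who this is for

Computational pathology groups who have per-slide tile-feature bags (one
d-dimensional embedding per 224-px tile, from any pretrained extractor), a
clinical covariate table, and right-censored outcomes (recurrence-free or
disease-specific survival), and who want to (a) train a tile-level
multiple-instance survival model, (b) compare and fuse it with a clinical
Cox model under a leakage-free repeated cross-validation protocol, and
(c) interpret the model tile by tile.

## The model

Each tile feature vector `x` gets a scalar score `s = g(x)` from a small
MLP; a slide is summarized by its sorted top-k and bottom-k tile scores; a
second MLP maps that 2k-vector to the slide risk; patient risk is the mean
over slides. Training minimizes a smooth concordance loss

    L = 1 - (1/|A|) * sum over admissible pairs (i,j) of sigmoid((r_i - r_j)/tau)

where a pair is admissible when `t_i < t_j` and patient *i* had the event,
so `1 - L -> ` Harrell's C-index as `tau -> 0`. The clinical arm is a Cox
proportional-hazards fit; the combined model averages the two predictions
after per-fold standardization on training-fold statistics. Evaluation: C-index
averaged over 5 stratified folds × 5 repeats, patient-level bootstrap with a
Z-test for model comparison, median-score stratification with Kaplan–Meier /
log-rank / hazard ratio. Per-tile attribution is the subset-sampling
difference-of-means value (tile in or out with probability 1/2, empty
subsets rejected), with an exact enumeration oracle for small bags.

## Worked example

The `analysis/` scripts run the full study on a synthetic cohort of 300
patients (1–3 slides each, 16-dim tile features, 10% planted signature
tiles in half the patients, independent clinical signal, ~30% censoring):

```sh
Rscript analysis/01_simulate.R    # cohort -> results/cohort/
Rscript analysis/02_models.R      # 5x5 repeated CV of all three models
Rscript analysis/03_evaluate.R    # C-indexes, bootstrap tests, KM/HR
Rscript analysis/04_attribution.R # tile contributions + enrichment
```

Output of stages 2–4 on this cohort (oracle C-index of the true log-hazard
0.819):

```
histologic  mean CV C-index 0.644 (sd over folds 0.055)
clinical    mean CV C-index 0.719 (sd over folds 0.026)
combined    mean CV C-index 0.760 (sd over folds 0.042)

histologic  C=0.644  HR=2.60 [1.94, 3.48]  logrank p=3.8e-11
clinical    C=0.719  HR=3.92 [2.87, 5.36]  logrank p=7.9e-20
combined    C=0.760  HR=5.04 [3.66, 6.93]  logrank p=1.1e-26
combined vs histologic: dC=0.1172, p=9.37e-14
combined vs clinical:   dC=0.0403, p=0.00689

signature tiles: 5.2% overall, 46.0% of top-100, 0.0% of bottom-100
```

Read: each single-modality arm recovers part of the planted signal; fusing
them lifts the C-index above both arms (bootstrap p = 0.007 vs the better
arm) and sharpens the median-split hazard ratio to 5.0; the attribution
step concentrates planted signature tiles 9-fold in the top-100
highest-contribution tiles and excludes them from the bottom-100.

Library use in three lines:

```r
library(milsurv)
cohort <- generate_cohort(cohort_spec(n_patients = 300, feature_dim = 16, seed = 1))
preds  <- predict_all_models(cohort, make_folds(cohort$outcomes, 5, 5, seed = 1),
                             mil_config(feature_dim = 16, seed = 1))
```

See `vignettes/milsurv-methods.Rmd` for the model, its assumptions, every
tunable parameter, and what the synthetic cohorts do and do not establish.

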
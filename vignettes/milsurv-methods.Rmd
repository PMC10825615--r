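---
title: "Tile-bag survival modeling with clinical Cox fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-bag survival modeling with clinical Cox fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milsurv)
```

## The problem

After liver resection or transplantation for hepatocellular carcinoma (HCC),
tumor recurrence is a leading cause of death, and the clinical question is
which patients need intensified surveillance or adjuvant therapy. Two kinds
of information are available at surgery: the H&E-stained tumor histology,
digitized as whole-slide images, and routine clinical covariates (serum AFP,
imaging findings such as multifocality, vascular invasion). `milsurv`
implements a complete pipeline that learns a prognostic score from each
modality, fuses them, and quantifies — with censoring-aware statistics —
whether the fusion improves prediction of recurrence-free survival (RFS) or
disease-specific survival (DSS).

Whole-slide images are far too large to model directly. The standard weakly
supervised treatment cuts the tissue into fixed 224-pixel tiles, embeds each
tile with a pretrained feature extractor, and treats a slide as a *bag* of
tile feature vectors with supervision only at the patient level (multiple-
instance learning, MIL). The feature extractor itself is outside this
package's scope: `milsurv` starts from tile-feature bags, which in real use
come from any upstream embedding network and in testing come from the
package's own synthetic generator.

## The tile-bag survival model

Each tile feature vector $x \in \mathbb{R}^d$ is mapped to a scalar tile
score $s = g_\theta(x)$ by a small multilayer perceptron (tanh hidden
units, linear output). A slide with tile scores $s_1, \dots, s_n$ is
summarized by its sorted top-$k$ and bottom-$k$ scores, and a second
perceptron $h_\phi$ maps this $2k$-vector to the slide risk. Patient risk is
the arithmetic mean over the patient's slides. The extreme-score
summarization is the canonical choice when a *minority* tile population
carries the signal: a prognostic pattern occupying a few percent of the
tissue moves the top of the score distribution long before it moves the
mean. It also makes the slide risk invariant to tile order and to bag size
by construction. Bags with fewer than $k$ tiles recycle their observed
extremes so the head's input size stays fixed.

Training maximizes ranking agreement with the observed survival times
directly, through a smooth relaxation of Harrell's concordance index:

$$\mathcal{L} = 1 - \frac{1}{|A|} \sum_{(i,j) \in A}
\sigma\!\left(\frac{r_i - r_j}{\tau}\right),$$

where $A$ is the set of admissible ordered pairs ($t_i < t_j$ and patient
$i$ had the event), $\sigma$ the logistic function, and $\tau > 0$ a
temperature. As $\tau \downarrow 0$ the summand becomes the hard
concordance indicator, so $1 - \mathcal{L}$ converges to the C-index; the
test suite verifies agreement to $10^{-6}$ at $\tau = 10^{-4}$. Pairs are
formed within minibatches of patients. Gradients flow through the head, the
sort-and-select step (a fixed permutation almost everywhere, so the gradient
passes to the selected tiles), and the tile scorer; the backward pass is
written out analytically and checked against finite differences to
$10^{-5}$. Optimization is plain Adam with fixed defaults
(`learning_rate = 0.01`, `batch_size = 32`) for 20 epochs from scratch or
10 epochs when fine-tuning from a pretrained model — fixed epoch budgets,
no early stopping, so runs are exactly reproducible from the seed.

Defaults that matter: `n_extreme = 25` (top and bottom 25 tile scores),
`scoring_hidden = 16`, `head_hidden = 8`, `tau = 1`. The temperature is
relative to the scale of the learned risks; 1 keeps gradients alive early
in training while the risk spread is small. These were chosen during model
development on synthetic cohorts and are deliberately small: the model has
a few hundred parameters, which is what a 200–500 patient cohort can
support.

## The clinical arm and the fusion

The clinical model is a Cox proportional-hazards fit (Efron tie handling,
complete cases) on the configured covariates; the AFP-like marker is
log-transformed by default because serum AFP spans four orders of magnitude.
Its prediction for a patient is the linear predictor $x^\top \hat\beta$,
centered on the *training* covariate means.

The combined model averages the two predictions. A Cox linear predictor and
an MIL risk live on incomparable scales, so the default standardizes each
arm by the mean and standard deviation of its *training-fold* predictions
before averaging with equal weights; a `raw_mean` mode is kept for
sensitivity analysis. Under rank-based evaluation the choice is low-stakes,
but it must be explicit — and it must use training-fold statistics only,
which the test suite asserts with a leakage negative control (recomputing a
held-out fold's combined scores with test-fold statistics changes them).

## Evaluation machinery

*Concordance.* A pair is admissible when the strictly shorter observed time
belongs to a patient with an event; tied times are never admissible (strict
inequalities), and tied risks on admissible pairs count 1/2. The
implementation is validated against an independent brute-force pair
enumerator on hundreds of random instances with censoring and ties.

*Cross-validation.* 5 folds × 5 repeats, stratified on the event indicator
so each fold sees the same censoring mix; the reported C-index is the
unweighted mean over the 25 folds (fold sizes differ by at most one, so
weighting is immaterial; unweighted is the simpler convention and is
logged).

*Model comparison.* Patients are resampled with replacement; per replicate
each fold's C-index is recomputed on the resampled membership using the
fixed out-of-fold predictions (no refitting — the resample is at the
evaluation level), folds are averaged, and a Z-test is applied to the
replicate differences. Replicates with no admissible pair anywhere are
redrawn. Identical prediction sets yield a degenerate zero distribution and
p = 1 by convention.

*Stratification.* The median of the pooled out-of-fold scores splits
patients into high/low risk (ties to low); the groups are compared with
Kaplan–Meier curves, a log-rank test, and a univariate Cox hazard ratio.
Pooling the out-of-fold scores is the only leakage-free way to get one score
per patient for this split.

## Tile attribution

The contribution of tile $i$ to a slide's prediction is defined over
subsets of the bag: the mean prediction over non-empty subsets containing
$i$ minus the mean over non-empty subsets not containing it. Subsets are
sampled by independent inclusion at probability 1/2 with empty draws
rejected — the uniform law over non-empty subsets. With uniform subset
weighting this is a Banzhaf-type value rather than the classical
Shapley weighting; the package implements the difference-of-means estimand
as defined and documents the distinction rather than silently substituting
one for the other. Exact enumeration ($2^N - 1$ predictions) is available
up to $N = 20$ tiles and serves as the oracle for the Monte-Carlo
estimator, which reports per-tile standard errors from the two group means.
For an additive predictor $f(S) = \sum_{i \in S} w_i$ the non-empty
convention gives the closed form
$w_i - \sum_{j \ne i} w_j / (2(2^{N-1}-1))$, which the tests assert
exactly, alongside the $w_i$ identity of the empty-set-included variant.

Because tile scores do not depend on the subset, the subset predictor
caches them once per bag and re-evaluates only the selection and the head,
making cohort-wide attribution cheap. Extreme tiles (top-100 and
bottom-100 by contribution, ties broken by slide and tile index) are
compared feature by feature with pooled two-proportion Z-tests and
Holm–Šidák step-down adjustment; with synthetic cohorts the planted
signature label plays the role of the pathologist's annotations.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
histology itself. Half the patients are signature carriers; each of a
carrier's tiles is a signature tile with probability `signature_fraction`
(default 0.1). Background tiles are standard Gaussian in feature space;
signature tiles are shifted by `signature_shift` (default 2) along one
fixed random unit direction. The patient's histologic signal is the
realized fraction of signature tiles across their bags — a bag-level
quantity, matching the MIL assumption that a minority tile population
carries prognosis. Clinical covariates are a log-normal AFP-like marker, a
Bernoulli invasion-like flag, and a shifted-Poisson tumor count; the true
log-hazard is $\eta = \beta_{hist}\,\tilde h + \beta_{clin}^\top \tilde x$
on standardized signals, with the two contributions independent by default
(a correlation knob exists for sensitivity work). Event times are
exponential with rate $\lambda_i = \lambda_0 e^{\eta_i}$ (Weibull shape 1:
closed-form sampling and analytic censoring); censoring is an independent
exponential whose rate is found by a 1-D root solve of
$\mathbb{E}[c/(c+\lambda_i)] = $ `target_censoring`, hitting any target
rate in $[0, 1)$ without truncation artifacts. All randomness flows from
one seed; the generated cohort is bit-reproducible.

Scale defaults are desk-scale study conditions chosen once: 300 patients
(the size of the larger cohort such a study would enroll), 1–3 slides per
patient, 50–150 tiles per slide, feature dimension 64 (16 in the
evaluation experiments below — large enough for a non-trivial signature
direction, small enough to keep a full repeated-CV run in minutes), 30%
censoring, baseline rate 0.02/month putting median event times near 35
months.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: feature distributions from real extractors are far
from Gaussian mixtures and their prognostic structure is not a single
linear direction; clinical covariates correlate with histology in patients;
censoring is administrative, not exponential; and proportional hazards is
an assumption, not a property of tumors. The synthetic results validate the
*machinery* (losses, folds, bootstrap, attribution), not clinical
performance.

## Numerical choices and degenerate inputs

- Tied times are inadmissible everywhere (strict-inequality rule); tied
  risks count 1/2 in evaluation and contribute zero gradient direction in
  the smooth loss.
- Batches with no admissible pair are skipped during training; a whole
  dataset without admissible pairs is an error, as is an all-censored fold
  (dropped with a warning in CV averaging).
- Median stratification with all-identical scores, Cox fits with constant
  columns or zero events, and empty bags after filtering are explicit
  errors, not silent degeneracies.
- Tile grids drop partial margin tiles (no padding rule is defensible
  without knowing the scanner geometry).
- Fold remainders go to the lowest-numbered folds; stratification keeps
  per-fold event counts within one.
- Parquet stores the per-slide feature matrices (bit-exact doubles,
  language-neutral); clinical and outcome tables are plain CSV.

## Problem sizes used in the shipped experiments

The analysis scripts and acceptance checks run at: n = 300 patients,
d = 16, 5-fold cross-validation (1 repeat in the seeded experiments, 5
repeats in `analysis/02_models.R`), bootstrap B = 500–2000, 300–500
sampled subsets per bag for attribution, and 50-seed replications for the
Cox recovery study. These sizes give Monte-Carlo error comfortably inside
the tolerances asserted while keeping a full run on one CPU in minutes.

## Known limitations

- The fine-tuning protocol transfers whole-model parameters only; there is
  no layer freezing or learning-rate scheduling.
- The bootstrap compares models at the evaluation level; it does not
  propagate training variability (refitting thousands of times is neither
  feasible nor implied by the protocol it mirrors).
- Attribution assumes the bag model is meaningful on sub-bags, which the
  extreme-score architecture supports but attention-style architectures
  might not.
- No proportional-hazards diagnostics, time-varying covariates, or
  competing-risks handling.
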
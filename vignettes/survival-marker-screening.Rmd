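---
title: "Survival-marker screening in merged multi-batch expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-marker screening in merged multi-batch expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscreen)
options(survscreen.verbose = FALSE)
```

## The problem

Prognostic ("survival-marker") genes for colorectal cancer are usually
sought in single cohorts of at most a few hundred tumors, which is why
published signatures overlap so poorly. Pooling several public microarray
series gives the sample size needed for a stable ranking, but introduces
two complications that this package addresses as first-class steps:

1. **Batch structure.** Each series carries its own location/scale
   artifacts. Merged matrices must be corrected, and the correction must be
   *verified* — here with a regression diagnostic and two mixing scores.
2. **Selection honesty.** Screening thousands of genes with a per-gene
   *optimal* expression cutpoint inflates significance. The pipeline
   compensates with a stringent adjusted-p threshold, resampling stability
   counts, and a cross-validated multivariate model.

The full stage order is: merge and filter → batch correction + diagnostics
→ stage-contrast differential expression → per-gene optimal-cutpoint
Kaplan–Meier screen → 80% resampling stability ranking → L1-penalized Cox
risk score with a cross-validated threshold.

## The data model

A `cohort` couples a log2 expression matrix (genes × samples) with a
phenotype table (`sample_id`, `batch_id`, `stage` I–IV/normal, `os_time`
in months, `os_event` 0/1). `filter_for_survival()` drops samples without
outcome data and normal tissue, and reports per-series bookkeeping
(total/discarded/processed) in an assembly manifest. Merging uses the
*intersection* of gene universes: with heterogeneous inputs the
intersection is the only semantics that cannot fabricate values. All
times are months; day-scale inputs are divided by 30.44 on read.

## Batch integration and its diagnostics

Two corrections are provided behind one interface:

* `mean_center_by_batch()` — per gene, each batch's mean is mapped to the
  gene's global mean. Exact for pure location artifacts; after it, every
  batch-dummy coefficient in the diagnostic regression is zero by
  construction.
* `eb_location_scale_adjust()` — the parametric empirical-Bayes
  location/scale adjustment: per-gene per-batch means and variances are
  estimated on pooled-standardized data, shrunk toward batch-level
  normal/inverse-gamma priors (moment-matched), and removed. With
  `shrink = FALSE` it degenerates to exact per-gene per-batch
  standardization, which is useful for testing and for very large batches
  where shrinkage is immaterial. The test suite cross-checks the default
  against an independent reference implementation to ~1e-6.

Whether correction *worked* is judged three ways, mirroring how merged
microarray studies are evaluated visually, but quantified:

* `batch_factor_regression()` — OLS of per-sample mean expression on
  batch dummies (first batch folded into the intercept). Any factor with
  p < 0.05 flags a remaining batch effect; a looser 0.20 level is
  reported as "marginal" without affecting decisions. The response is the
  per-sample mean over genes (not gene-wise regressions averaged): the
  diagnostic targets global signal-distribution shifts, which is also
  the cheaper and more interpretable reading.
* `mixing_diagnostics()` — on a balanced subsample (default 30 samples
  per batch), average-linkage clustering under 1 − Pearson correlation
  cut at K = #batches gives a *clustering purity* (fraction of samples
  whose cluster is dominated by their own batch), and the mean silhouette
  of batch labels on the first two principal components gives a
  *PCA silhouette*. Defaults of purity < 0.6 and |silhouette| < 0.1 are
  sensible "well-mixed" guides; both are config, not hard gates.

Pearson correlation is invariant to sample-wide location shifts, so the
purity score responds to gene-*profile* batch structure (the realistic
case), not to a uniform offset alone.

## Stage contrast

`stage_contrast()` compares late (III/IV) against early (I/II) tumors with
per-gene linear models and empirical-Bayes variance moderation (prior df
and prior variance estimated by moment matching on log sample variances;
the limma machinery). The significant set at FDR ≤ 0.01 (Benjamini–
Hochberg), split by direction, is the usual input universe for the
survival screen. The package also exposes `moderated_t()`, an explicit
formula-level implementation used to verify the two limits: zero prior
weight reproduces the ordinary pooled t exactly, infinite prior weight
uses the prior variance alone. A repeated tumor-versus-normal comparison
(`tumor_vs_normal_panels()`, default 20 repeats of 25 vs 25) summarizes,
per gene, how often the tumor median exceeds the normal median.

The DE threshold is a config value: the default is the stricter FDR 0.01;
0.05 is a documented alternative reading. The stage contrast runs on the
corrected matrix without a batch covariate — correction and testing are
deliberately separated so the diagnostics above certify the former.

## The optimal-cutpoint screen

For each gene, samples are sorted by expression and every admissible
split position `k` with `ceil(0.25 n) ≤ k ≤ floor(0.75 n)` defines
low/high groups (ties never split; the quantile bounds are inclusive —
the endpoint convention is fixed for determinism). The log-rank
chi-square of every candidate split is computed in a single vectorized
pass from cumulative risk-set and event-count matrices; this reproduces
the classical statistic exactly (the suite checks equality with
brute-force risk-set enumeration at 1e-10 on small instances). The
minimum-p split wins; ties prefer the more balanced split, then the lower
`k`. The cut value is the midpoint of the adjacent distinct expression
values, so the procedure is invariant under strictly monotone transforms
of a gene's values. The hazard ratio is a Cox fit (Efron ties) on the
high-group indicator: HR > 1 means high expression is hazardous.

Minimum-p selection is *not* corrected within a gene; instead the
across-gene BH adjustment is taken at a deliberately stringent default
(adjusted p < 3e-4), and stability resampling does the real policing:
`stability_resample()` redraws 80% of subjects 100 times, re-optimizes
the cutpoint and re-applies BH within each iteration over the same gene
universe, and counts significant iterations; genes above 80/100 are
retained. Re-optimizing per iteration (rather than freezing the full-data
cutpoint) is the point — the stability of the *whole procedure* is what
is being measured. `rank_markers()` then ranks retained genes by the
whole-data log-rank p within each direction, ties broken by larger
|log HR|.

## The multivariate risk score

`fit_l1_cox()` takes the top up-regulated/poor-prognosis genes (default
100), standardizes each (training mean/SD), and fits an L1-penalized Cox
model along a lambda path, with lambda chosen by 10-fold cross-validated
partial likelihood. Continuous standardized expression enters the model —
dichotomization is only a univariate screening device. The risk score is
the linear predictor; `score_and_threshold()` finds the score threshold
by a second, separate 10-fold cross-validation: a 41-point grid of score
percentiles (10–90%) is evaluated by held-out log-rank chi-square,
the grid is re-laid between the neighbors of the argmax, and the search
repeats (`refine_rounds`, default 1). Candidates leaving a fold's group
empty are skipped for that fold. Lambda and the threshold are
cross-validated separately, by design: they answer different questions
(model complexity vs decision boundary). Near a flat optimum the chosen
threshold can wobble by a boundary sample between reruns with different
fold seeds; with a fixed seed the search is exactly reproducible.
Breslow ties are used inside the penalized fit, Efron in the final
reported Cox on the group indicator.

## The synthetic cohort generator

`generate_cohort()` draws `x[g,s] = mu_g + stage_shift_g·late_s +
tumor_effect_g·tumor_s + loc_b + offset[g,b] + eps`, with per-gene noise
`eps ~ N(0, sigma_g·scale_b)`; survival times come by inverse transform
from a proportional-hazards model whose linear predictor sums
`beta_m · z[m,s]` over marker genes, `z` the standardized *batch-free*
expression (batch artifacts are technical, so they do not enter the
hazard). Defaults: gene means N(7, 1) and noise SDs lognormal around 0.5
(the scale of log2 microarray summaries); batch location and per-gene
offsets share one SD (0.3); baseline hazard 0.01 events/month with a
120-month administrative horizon; 40% late-stage; marker effect log(2)
per SD; censoring 60% — a free choice in the plausible range for
colorectal OS cohorts, fixed once. Random censoring is calibrated by
solving the exact exponential-model censoring probability (including the
administrative cap) for the censoring rate; when the cap alone censors
more than the target, the random component is zero and the realized
fraction exceeds the target — the Weibull shape option reuses the same
calibration as an approximation.

Marker and stage gene sets are disjoint by default, so stage is
independent of survival and markers are the only prognostic genes — the
cleanest recovery test. With `markers_stage_shifted = TRUE` markers also
carry the late-stage shift: they then pass a stage-DE pre-filter, but
stage couples to the hazard and stage-shifted genes become genuinely
prognostic too, which matters when interpreting recovery counts.

What the generator does *not* emulate: probe-level artifacts, non-Gaussian
heavy-tailed noise, gene–gene correlation beyond the shared stage/batch
structure, informative censoring, and non-proportional hazards. Passing
recovery tests therefore certify the pipeline's statistical machinery,
not its robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Cox fits: Newton–Raphson with tolerance 1e-9, up to 50 iterations;
  monotone likelihood (perfect separation) is flagged and the coefficient
  capped at |beta| = 20 rather than silently diverging; constant
  covariates are an error.
* Log-rank variance uses the hypergeometric form with the `n−1`
  denominator; a candidate split with zero variance gets p = 1.
* Constant genes are skipped in the screen with reason `no_valid_cut`;
  genes constant within one batch get location-only EB adjustment;
  all-constant genes pass through correction unchanged.
* BH adjustment is the standard step-up; the adjustment method for the
  survival screen is a configurable choice, BH by default.
* All stage randomness flows from one master seed through fixed named
  substreams, so any stage can be re-run in isolation bit-identically.

## Problem sizes used in the checks

The packaged tests run the recovery study at 2000 genes × 800 samples ×
6 batches with 20 planted markers (HR 2 per SD, 60% censoring) over 5
seeds, with stability scaled to 25 iterations (retain threshold 20) on
the screen's top genes plus the markers and a 50-gene null reference —
sizes chosen so the full suite completes comfortably on one CPU while
keeping per-seed power high. The bundled acceptance script runs the same
design once at 7 batches and reports the measured quantities as JSON.

## Known limitations

* The minimum-p cutpoint p-values are anti-conservative per gene; they
  are meant for *ranking*. An optional permutation calibration is the
  obvious extension and is not implemented.
* The EB adjustment assumes roughly normal per-batch effects across
  genes; wildly non-normal batch artifact distributions would call for
  the non-parametric prior variant.
* The threshold search optimizes a single split; three-group (low /
  intermediate / high) stratification is out of scope.
* Stage must be provided as I–IV; TNM parsing is out of scope.
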
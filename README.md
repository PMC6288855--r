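# survscreen

Discovery of prognostic (survival-marker) genes in colorectal cancer from
merged multi-batch transcriptomic cohorts. Published CRC signatures are
trained on small single cohorts and barely overlap; pooling several public
series fixes the power problem but raises two new ones — batch artifacts
in the merged matrix, and the selection bias of screening thousands of
genes with per-gene *optimal* expression cutpoints. `survscreen`
implements the full pipeline that addresses both, for analysts working
with expression + overall-survival cohorts:

1. **Cohort assembly** — TSV expression/phenotype pairs, merging on the
   common gene universe, survival filtering with per-series bookkeeping.
2. **Batch integration** — per-batch mean-centering or a parametric
   empirical-Bayes location/scale adjustment, verified by a batch-dummy
   regression on per-sample mean expression and by two mixing scores
   (clustering purity under 1 − Pearson distance; batch-label silhouette
   on the first two principal components).
3. **Stage contrast** — moderated-t differential expression of late
   (III/IV) vs early (I/II) tumors at FDR ≤ 0.01, plus a repeated
   tumor-vs-normal panel comparison.
4. **Optimal-cutpoint screen** — per gene, the expression threshold in
   the 25–75% quantile band minimizing the two-group log-rank p-value
   (KM separation), with Cox hazard ratios (HR > 1 ⇔ high expression is
   hazardous) and BH adjustment across genes at a stringent 3e-4.
5. **Stability ranking** — 100 redraws of 80% of subjects, cutpoint
   re-optimized and BH re-applied within each redraw; genes significant
   in > 80 iterations are retained and ranked.
6. **Risk predictor** — an L1-penalized multivariate Cox model on the
   top up-regulated/poor-prognosis genes (standardized expression,
   lambda by 10-fold CV), and a risk-score threshold chosen by a second
   10-fold CV maximizing held-out log-rank separation on a refined
   percentile grid.

The statistical core is the per-gene minimum-p-value split
`chi^2 = (sum_j (O_1j - E_1j))^2 / sum_j V_j` over pooled event times,
scanned in one vectorized pass per gene across all admissible splits, and
the proportional-hazards machinery around it. A synthetic multi-batch
cohort generator with known ground truth (planted marker effects, batch
offsets, calibrated censoring) makes every stage testable offline.

## Worked example

Simulate a 4-batch cohort with 8 planted markers tied to the late-stage
program, run the whole pipeline, and inspect the recovery:

```r
library(survscreen)

spec <- synthetic_spec(n_genes = 1000, n_samples = 400, n_batches = 4,
                       n_marker_genes = 8, marker_beta = log(1.6),
                       n_stage_genes = 60, stage_effect = 0.4,
                       markers_stage_shifted = TRUE, seed = 7)
gen <- generate_cohort(spec)

cfg <- pipeline_config(batch_method = "eb", resample_iter = 25,
                       retain_min = 15, screen_p_adj_cut = 0.001,
                       stability_genes = 60, top_k = 25, folds = 5, seed = 7)
res <- run_pipeline(gen$cohort, cfg)

res$diagnostics$mixing_before
#> mixing report: purity 0.750, PCA silhouette 0.905 (30/batch, 4 batches)
res$diagnostics$mixing_after
#> mixing report: purity 0.275, PCA silhouette -0.073 (30/batch, 4 batches)

head(res$ranking$up_poor[, c("rank","gene_id","km_p","hr","n_signif","hr_mean")], 5)
#>   rank gene_id         km_p       hr n_signif  hr_mean
#> 1    1  G00298 2.486487e-20 3.966642       25 4.082130
#> 2    2  G00706 3.487523e-16 3.399707       25 3.385688
#> 3    3  G00615 1.851449e-15 3.677574       25 3.703686
#> 4    4  G00515 1.493076e-14 3.255136       25 3.340656
#> 5    5  G00783 2.019215e-14 3.228933       25 3.413803

m <- res$risk_model
sprintf("risk split: %d high / %d low, log-rank p = %.3g, HR = %.2f",
        m$n_high, m$n_low, m$separation$logrank_p, m$separation$hr)
#> "risk split: 87 high / 313 low, log-rank p = 8.02e-75, HR = 14.46"
```

Reading the output: the EB adjustment takes the batch-label silhouette
from 0.905 (batches dominate the PCA plane) to −0.073 (well mixed) before
any testing. The ranked table is the marker shortlist — `km_p`/`hr` come
from the whole-cohort optimal split, `n_signif` counts significant
resampling iterations (here 25 of 25: maximally stable), `hr_mean` is the
mean HR over redraws. All 8 planted markers end up among the ranked
genes; the separation of the two risk groups is far stronger than any
single gene because stage couples the markers to the hazard in this
simulation. A thin CLI for simulation and full runs is installed at
`inst/cli/survscreen.R` (`simulate`, `run-all`).

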
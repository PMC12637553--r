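# spanmf

Probabilistic factor analysis and regional convergence statistics for
imaging-based spatial transcriptomics panels.

## What this package is for

Targeted spatial assays (Xenium-style) deliver raw transcript counts for a
few hundred panel genes in millions of segmented cells across tissue
sections. When the panel encodes a gene family of interest — the motivating
use case is autism susceptibility genes across the mid-gestation human
brain — the analysis question is whether expression of those genes
converges on particular anatomical regions, and whether regionally enriched
gene sets carry distinct rare-variant risk. `spanmf` provides the full
chain:

* **Technical-variation-aware NMF.** Raw counts are modeled as
  `X_cg ~ NB(mu = l_c (S_eg + sum_f W_cf H_fg), alpha = a_g)`: non-negative
  cell loadings `W` and gene loadings `H`, per-cell detection efficiency
  `l_c`, per-section×gene ambient background `S_eg`, per-gene Negative
  Binomial concentration `a_g`. Fitted by stochastic gradient MAP (Adam,
  compiled gradients), with automatic relevance determination so surplus
  factors collapse, and a 99.9%-quantile activity score with a 2-means
  split to call active factors.
* **Factor summaries.** Region × factor mean reconstructed counts and
  proportions; per-gene *relative loadings* (share of region-averaged
  expression explained by each factor) with factor-enrichment (>33%) and
  robust-expression (median-of-maxima threshold) calls; assignment of
  multi-enriched genes to their strongest factor; Fisher tests of
  functional-category enrichment.
* **Regional statistics.** A deviation-coded binomial GLM asking, per
  region, whether susceptibility-gene detection per cell is above the
  average (BH-FDR across regions); Wilcoxon rank-sum regional markers with
  seeded, section-stratified subsampling (25,000-cell cap per region).
* **DNM burden.** Observed vs expected protein-truncating de novo mutation
  counts per gene set (`expected = 2 N sum(rates)`, Garwood intervals) and
  pairwise relative risks with the exact conditional Poisson test,
  Bonferroni-corrected.
* **Synthetic data.** `simulate_dataset()` runs the generative model
  forward (shared mean-function code path with the fitted model) so every
  stage is testable against ground truth; `simulate_dnm_cohort()` does the
  same for burden tests.

## Worked example

```r
library(spanmf)

# simulate a small multi-section dataset with 3 planted regional programs
cfg <- simulation_config(n_cells_per_region = 300,
                         regions = c("thalamus", "germinal zones",
                                     "cortical plate"),
                         n_factors_true = 3, n_genes = 50, n_batches = 2,
                         seed = 15)
sim <- simulate_dataset(cfg)
sim$data
#> ExpressionMatrix: 900 cells x 50 genes
#>   sections: 2  regions: 3  susceptibility genes: 40

qc <- filter_cells(sim$data, max_transcripts = 1000)
m  <- nmf_fit(qc$data, genes = seq_len(50),
              config = training_config(n_factors_init = 6, epochs = 2500,
                                       learning_rate = 0.01, seed = 2))
mask <- select_active_factors(m)
sum(mask)
#> [1] 3
m <- prune_factors(m, mask)

rs <- region_factor_summary(m, qc$data)
round(rs$proportions, 2)
#>                factor1 factor2 factor3 background
#> cortical plate    0.00    0.82    0.01       0.18
#> germinal zones    0.81    0.00    0.01       0.18
#> thalamus          0.00    0.00    0.85       0.15

lt <- assign_overlapping_genes(relative_gene_loading(m, qc$data))
sets <- factor_gene_sets(lt)      # disjoint per-factor gene sets
lengths(sets)
#> factor1 factor2 factor3
#>       8       9       8

det <- detection_counts(qc$data)
glm <- fit_detection_glm(det, sum(qc$data$genes$is_susceptibility),
                         qc$data$cells)
glm$regions[, c("region", "estimate", "q_value", "direction")]
#>           region    estimate      q_value direction
#> 1 cortical plate  0.02871574 6.981759e-02     above
#> 2 germinal zones -0.09203730 2.700409e-08     below
#> 3       thalamus  0.06332156 9.139985e-05     above
```

Each row of `rs$proportions` is the share of a region's reconstructed
panel expression explained by each factor plus the ambient background; the
planted one-factor-per-region structure is recovered (the estimated
ambient share also absorbs the diffuse low-level expression every cell
carries, which is indistinguishable from ambient within a section). The
GLM table reports each region's log-odds deviation from the across-region
average detection rate with its BH-adjusted q-value; the thalamus, with
the highest detection rate in this simulation, is flagged "above" at
q < 1e-4. (Numbers are from the seeds shown; factor order within a fit is
arbitrary.)

A YAML-driven end-to-end run (simulate → qc → fit → summarize →
enrich-regions → de-regions → dnm-burden) is available as
`run_pipeline("config.yaml")` or through the thin CLI wrapper
`inst/cli/spanmf.R`; see `inst/extdata/pipeline_small.yaml` for a complete
small configuration.

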
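# hvsvbench

Benchmarking whether **concatenating highly variable (HV) genes with
spatially variable (SV) genes improves cell-type clustering** in spatial
transcriptomics data.

Spatial transcriptomics assays yield a UMI count matrix together with the
spatial position of every cell or spot. Clustering pipelines must first
choose *features*: conventionally the HV genes (expression variance in
excess of what the mean predicts), or — specific to spatial data — the SV
genes (expression with significant spatial autocorrelation). The two sets
are often largely distinct. This package implements a replicated,
fully-seeded benchmark that measures the clustering payoff of using the
deduplicated union of both sets ("concatenation"), against either set
alone and against size-matched random "ground control" gene sets, on
synthetic tissues where the true cell types are known by construction.

## What is inside

* **Synthetic data generator** — negative-binomial UMI counts over
  Voronoi spatial domains; cell types that are spatially segregated or
  dispersed; gene classes that are HV-detectable, SV-detectable, both, or
  neither; rare types and low-expression outliers
  (`complementarity_config()`, `generate_dataset()`).
* **Preprocessing** — Tukey-fence outlier removal for genes and cells,
  rare-type filtering (< 5 %), log-normalization, and analytic Pearson
  residuals `r = (x − μ)/√(μ + μ²/θ)` with `μ = rowsum·colsum/total`,
  `θ = 100`, clipped at ±√n.
* **Feature selection** — HV genes by residual variance > 1 with
  50/70/90th-percentile low/medium/high thresholds, or by LOESS
  coefficient-of-variation excess; SV genes by a permutation-tested
  Moran's I, `I = (n/S₀)·zᵀWz / zᵀz`, on row-standardized symmetrized kNN
  spatial weights (a pluggable stand-in for external SV detectors);
  concatenation and random ground controls.
* **Clustering** — PCA → shared-nearest-neighbor graph (Jaccard edge
  weights, k = 15) → Leiden with a resolution grid search and a 10-seed
  majority (ARI-medoid) vote at the ground-truth cluster count; kmeans
  with Euclidean / Pearson / Spearman distances as the secondary method.
* **Metrics** — AMI (permutation-model adjusted), weighted F1 after
  optimal expression-centroid cluster matching, Pearson Gamma, and the
  two entropy-weighted spatial metrics: **Spatial Concordance**
  `SC = Σᵢ 1[uᵢ = u*ᵢ]·e*ᵢ` and **mean spatial AMI**, where `e*ᵢ` are
  normalized Shannon entropies of the truth labels inside each cell's
  square spatial window (half-side = 1st percentile of pairwise
  distances) — so correct calls on domain borders count most.
* **Benchmark driver** — replicated runs, binomial depth-downsampling,
  paired two-sided Wilcoxon signed-rank comparisons with conventional
  significance stars (`run_benchmark()`).

The numbered scripts under `analysis/` run the full study:
`01_simulate_data.R` (one replicate as a portable bundle),
`02_feature_selection.R` (HV/SV capture per gene class),
`03_benchmark.R` (the 20-replicate headline comparison),
`04_depth_robustness.R` (thinned-counts robustness). Results land under
`results/`.

## A worked example

One replicate of the default scenario: 2000 cells, 300 genes, two
spatially segregated types separable only through weak spatial markers,
two dispersed types separable only through strong non-spatial markers.

```r
library(hvsvbench)

cfg <- complementarity_config(seed = 1)
gen <- generate_dataset(cfg)
ds  <- filter_rare_types(filter_outliers(gen$dataset))

resid <- pearson_residuals(ds)
hv <- select_hvg_residual_variance(resid, level = "LOW")
sv <- select_svg_moran(resid, ds$coords, level = "LOW",
                       n_perm = 199, k_w = 30, seed = 7)
cc <- concatenate_selections(hv, sv)
print(hv); print(sv); print(cc)
#> <gene_selection> HVG_RESID/LOW: 67 genes
#> <gene_selection> SVG_MORAN/LOW: 83 genes
#> <gene_selection> CONCAT/NA: 133 genes

bc  <- benchmark_config(list(rep1 = cfg), master_seed = 42)
row <- rbind(run_condition(ds, "HV", bc, "rep1"),
             run_condition(ds, "SV", bc, "rep1"),
             run_condition(ds, "CONCAT", bc, "rep1"))
reshape(row[, c("condition", "metric", "value")],
        idvar = "condition", timevar = "metric", direction = "wide")
#>  condition value.AMI value.WF1 value.PGAMMA value.SC value.MSAMI
#>         HV     0.550     0.764        0.443    0.766       0.546
#>         SV     0.457     0.770        0.173    0.744       0.438
#>     CONCAT     0.738     0.906        0.466    0.910       0.731
```

HV genes resolve the dispersed types but blur the two segregated types;
SV genes do the reverse; their concatenation separates all four — higher
on every supervised metric, and highest exactly where the spatial
metrics look (SC = 0.91: the domain borders are called correctly).
`analysis/03_benchmark.R` repeats this over 20 seeded replicates and
confirms the ordering with paired Wilcoxon tests (p = 2⁻²⁰·2 ≪ 0.05 when
the concatenation wins every replicate).

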
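# lymphochemnet

Chemokine-centric analysis of lymph node (LN) organization and its loss in
lymphoma.

Secondary lymphoid organs owe their architecture to a handful of chemokine
gradients: follicular dendritic cells (FDCs) secrete CXCL13 and recruit
CXCR5⁺ B cells into follicles, T-zone fibroblastic reticular cells (FRCs)
secrete CCL19/CCL21 for CCR7⁺ T cells, and CXCL12 from stroma and
endothelium engages CXCR4. In diffuse large B cell lymphoma (DLBCL) this
homeostatic program collapses: remodeled FRCs switch to the
interferon-inducible ligands CXCL9/10/11, cytotoxic T cells up-regulate
CXCR3, and the follicle/T-zone zonation is effaced. `lymphochemnet`
implements the computational toolkit for studying this process from
single-cell expression, segmented spatial imaging data and bulk survival
cohorts, together with a fully specified synthetic LN generator so every
stage can be validated against planted ground truth.

## What it computes

**Cell-pair attraction potentials.** For every ordered (sender, receiver)
pair of cells in a sample and every ligand–receptor pair (l, r) in a curated
chemokine registry, the attraction potential is the geometric mean

> a(i→j; l, r) = √( xᵢ(l) · xⱼ(r) )

on log-normalized expression x. Pairs supported by fewer than 4 positive
ligand–receptor scores are discarded; per-sample matrices are merged,
embedded with PCA (20 components) and a cosine k-nearest-neighbor graph
(k = 30), and clustered by modularity community detection. Clusters are
annotated by their dominant axis (CXCL13–CXCR5 → follicle, CCL19/21–CCR7 →
T zone, CXCL9/10/11–CXCR3 → inflammatory).

**Diffuseness score.** Interaction heterogeneity per patient is the mean
Euclidean distance between pair feature vectors in PC space after random
downsampling to 30% — near zero for a tissue dominated by one or two
homogeneous interaction programs, high for the fragmented interaction
landscape of DLBCL.

**Spatial neighborhoods.** For segmented cells with μm coordinates, each
cell's k = 20 nearest-neighbor cell-type composition vector is clustered
(k-means, k = 20), redundant clusters are binned by centroid correlation,
and cell-type enrichment per neighborhood is scored as log₂ odds ratios with
Fisher exact tests (BH-adjusted). Marker positivity uses Otsu thresholding;
ligand–receptor proximity counts partner cells within a 20 μm radius; and a
Gaussian-KDE attraction test asks whether receptor-positive target cells
accumulate around ligand-positive senders (Wilcoxon rank-sum on interpolated
densities).

**Survival stratification.** Bulk cohorts are scored by the mean expression
of the homeostatic (CXCL12, CXCL13, CCL19, CCL21) or inflammatory
(CXCL9/10/11) signature and dichotomized with maximally selected rank
statistics (standardized log-rank statistic maximized over candidate
cutpoints, selection-aware permutation p), followed by Kaplan–Meier curves
and the log-rank test.

## Worked example

```r
library(lymphochemnet)

# synthetic reactive lymph node: 1000 cells with stroma-anchored
# homeostatic chemokine programs
ds   <- generate_expression(entity_profile("rLN"), n_cells = 1000, seed = 42)
expr <- log_normalize(ds$expression)

pm  <- compute_attraction(expr, ds$cells, lr_registry(),
                          downsample_per_type = 30, seed = 42)
pm  <- filter_pairs(pm, 4)
emb <- embed_pairs(pm, analysis_config(), layout = "none")
emb <- cluster_pairs(emb, resolution = 0.3, seed = 42)
emb <- annotate_clusters(emb)
head(subset(emb$zone, zone != "other"), 4)
#>    cluster       top_lr     zone
#> 5        5 CXCL13_CXCR5 follicle
#> 59      59   CCL21_CCR7   t_zone
#> 60      60   CCL21_CCR7   t_zone
#> 77      77   CCL21_CCR7   t_zone

diffuseness(emb, entity = "rLN", seed = 42)
#>   patient entity n_used    score
#> 1 rLN_s42    rLN  17404 12.28413
```

The follicular CXCL13–CXCR5 and T-zone CCL21–CCR7 interaction programs are
recovered as separate pair clusters, and the diffuseness score (12.3)
provides the reactive-tissue baseline against which FL and DLBCL cohorts
score progressively higher.

Survival stratification on a synthetic cohort with a planted hazard ratio
of 3 below the 60th score percentile:

```r
surv <- generate_survival(600, effect = log(3), censor_fraction = 0.2,
                          cutpoint_quantile = 0.6, seed = 42)
ms <- maxstat_cutpoint(surv, n_perm = 999, seed = 42)
# cutpoint 0.258 (64th percentile), max statistic 11.56, permutation p 0.001
surv$group <- ms$group
km <- km_logrank(surv)
round(km$median_by_group, 1)
#> high  low
#> 67.3 18.8     # months; log-rank chisq 138.4, p 6.0e-32
```

The recovered cutpoint sits at the 64th percentile (planted: 60th) and the
low-signature group's median survival is about a third of the high group's,
matching the planted hazard ratio.

A complete run (synthesize → attraction → pairspace → spatial → signatures)
is driven by `run_pipeline()` or the thin CLI in `inst/cli/lymphochemnet`;
identical configuration and seed give byte-identical outputs.

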
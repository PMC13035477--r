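---
title: "Methods: chemokine attraction, spatial neighborhoods and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemokine attraction, spatial neighborhoods and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `lymphochemnet`, the parameters
that matter, the synthetic data the package validates itself on, and the
numerical decisions taken where the underlying procedures are usually left
underspecified.

## 1. The attraction-potential model

Lymph node zonation is maintained by stromal chemokine gradients. We model
the *potential* for chemotactic interaction between two cells — not the
physical gradient — as a feature vector over ligand–receptor (L–R) axes.
For sender cell $i$, receiver cell $j$ and registry axis $(l, r)$,

$$a_{i \to j}(l, r) \;=\; \sqrt{x_i(l)\, x_j(r)},$$

where $x$ is log-normalized expression,
$x_{gc} = \ln\!\big(1 + s\, n_{gc} / N_c\big)$ with scale $s = 10{,}000$.
The scale factor is a community convention rather than a derived constant;
it is configurable in `log_normalize()` and only shifts all scores
monotonically. The geometric mean is zero whenever either side is silent
(an absorbing zero: no ligand, no attraction), is symmetric in its two
inputs but *directed* in its indexing ($a_{i\to j} \ne a_{j\to i}$ unless
expression happens to be balanced), and is homogeneous of degree one —
multiplying expression by $c$ multiplies every score by $c$. All three
properties are asserted in the test suite.

Scores are computed within samples only; per-sample matrices are
concatenated afterwards (`merge_samples()`), so no cross-sample pair ever
exists. Rows with fewer than `min_lr_pairs = 4` strictly positive axes are
discarded (`filter_pairs()`): a pair supported by a single axis carries no
profile to embed. The pair count grows as $n(n-1)$ per sample, so
`compute_attraction()` caps cells per annotated type
(`downsample_per_type`, default 100, seeded) — results at desk scale are
insensitive to this cap because scores are computed per pair, not per
population.

The bundled registry holds 15 chemokine axes: the four homeostatic ones
(CXCL13–CXCR5, CXCL12–CXCR4, CCL19/CCL21–CCR7), the three
interferon-inducible inflammatory ones (CXCL9/10/11–CXCR3) and eight
constitutive axes (CCL2/3/4/5/17/20/22, CXCL16 and their receptors).
Published registries of "chemokine-related" pairs vary in size (different
curations count 50–70 axes, and even a single study may quote different
numbers for database content and analysis input); the registry here is
therefore data, not a constant — `lr_registry(path)` accepts any CSV of
`ligand,receptor,class`. Multi-subunit receptors are out of scope: every
axis is one ligand gene and one receptor gene.

## 2. Pair embedding, clustering, annotation

The filtered score matrix is treated as a feature matrix over pairs: PCA
(centered, not variance-scaled — the score scale is meaningful) to
`n_pcs = 20` components, clamped to the number of columns when the registry
is narrower; then a cosine k-nearest-neighbor graph (`knn = 30`) on PC
coordinates; then modularity community detection (multilevel/Louvain) on
that graph. The clustering algorithm is a package choice: it operates on
the graph the embedding already builds, its resolution parameter is exposed
(`cluster_pairs(resolution=)`), and at desk scale (10⁴–10⁵ pairs) a
resolution of 0.2–0.5 yields interpretable zone-level clusters while the
default 1 gives finer programs. An optional 2-D force-directed layout of
the same graph (`layout = "fr"`) serves visualization only; no quantity is
computed from it.

Clusters are annotated by their top mean-scoring axis: CXCL13–CXCR5 marks
follicle-like clusters, CCL19/21–CCR7 T-zone-like, CXCL9/10/11–CXCR3
inflammatory. Ties break lexicographically (deterministic and logged);
all-zero clusters are `unassigned`.

## 3. The diffuseness score

Per patient, pairs are randomly downsampled to `fraction = 0.3`, and the
score is the mean Euclidean distance over all unordered sampled pairs in PC
space — computed exactly (a compiled $O(m^2)$ kernel), not approximated.
The score is 0 iff all sampled vectors coincide, is translation-invariant,
and scales linearly with coordinates; the suite asserts all three plus
agreement with a brute-force oracle at $10^{-9}$. Whether to compute PC
coordinates per entity or on the merged embedding is ambiguous in common
practice; we use the merged PC space and group afterwards, so scores of
different patients are distances in one common geometry and remain
comparable across entities.

## 4. Spatial neighborhoods

Each segmented cell is summarized by the cell-type composition of its
`nhood_k = 20` Euclidean nearest neighbors (self excluded; distance ties
broken by cell order, so results are permutation-stable). Compositions are
clustered with k-means (`nhood_kmeans_k = 20`, 5 restarts under a fixed
seed), and redundant clusters are binned: while any two centroids have
Pearson correlation at or above `similarity_threshold`, the closest pair
merges and its centroid is recomputed (cell-weighted), to a fixed point.

The merge threshold deserves a note. With $k = 20$ neighbors a composition
entry carries multinomial noise of $\sqrt{p(1-p)/20} \approx 0.1$, which is
the same order as the spread *between* cell-type proportions within one
microdomain. Empirically, k-means subclusters of one planted zone have
centroid correlations ranging from about 0.6 to 0.97, while centroids of
distinct zones stay below about 0.5. A threshold of 0.9 therefore leaves
single zones fragmented; the default is 0.75, comfortably above cross-zone
similarity and tolerant of within-zone sampling noise. It is a parameter,
not a constant.

Enrichment per (neighborhood, type) is the log₂ odds ratio of the 2×2
in/out table, with a Haldane–Anscombe 0.5 correction applied only when a
cell is zero, plus the two-sided Fisher exact p, BH-adjusted over the whole
matrix. `annotate_neighborhoods()` maps neighborhoods to zones through
their most-enriched structural type (FDC → follicle, FRC → T zone, rFRC →
inflammatory, LEC/macrophage → sinus).

Marker positivity uses Otsu's threshold on a 256-bin histogram (maximal
between-class variance; first maximum wins on plateaus — a deterministic
tie rule that matters for widely separated modes, where the variance is
flat across the empty gap). Radius-based L–R proximity counts, per cell,
partners within `lr_radius_um = 20` that complete the axis in either
orientation; each qualifying pair increments both cells once. The KDE
attraction test evaluates an isotropic Gaussian KDE of target-cell
positions at ligand-positive and ligand-negative sender positions and
compares the two density samples by Wilcoxon rank-sum. The bandwidth
defaults to Silverman's rule (geometric mean of the per-axis values) and
is overridable in μm; the single-point closed form $1/(2\pi h^2)$ anchors
the implementation in a test.

Transcript-based positivity follows platform conventions: raw count ≥ 1
when counts are given, normalized expression > 2 when normalized values are
given; spatial QC keeps cells with strictly more than `min_transcripts = 50`
transcripts.

## 5. Signature scores and survival

Signature scores are unweighted means of the signature genes' normalized
expression (homeostatic: CXCL12, CXCL13, CCL19, CCL21; inflammatory:
CXCL9/10/11). For stratification, `maxstat_cutpoint()` computes, for each
candidate cutpoint between the `min_group_fraction = 0.1` and 0.9 score
quantiles, the standardized log-rank statistic of the induced split: the
log-rank scores are martingale residuals of the pooled Nelson–Aalen
estimator ($a_i = \delta_i - \hat\Lambda(t_i)$, ties handled), the group
sum is standardized by its exact permutation variance
$m(n-m)\,\Sigma a_i^2 / (n(n-1))$, and the cutpoint maximizing $|z|$ is
selected. Because the maximum over cutpoints is not a fixed-split log-rank
statistic, reference implementations offer several approximations for its
null distribution; we instead report a selection-aware p from a seeded
permutation of score labels (default 1000 permutations, p of the form
$(1+B)/(n_{perm}+1)$), alongside the naive log-rank p of the selected
split, clearly labelled — the permutation p is the honest one. The
candidate set is rank-based, so the procedure is invariant under monotone
transformations of the score. Kaplan–Meier estimation and the two-group
log-rank test use the survival package.

Clonotypes are "expanded" when observed in strictly more than 7 cells;
regulon–target enrichment is a Fisher exact test on a fixed gene universe
with Bonferroni adjustment across regulons in batch mode. Cox models are
out of scope; the stratified table is exposed for external fitting.

## 6. What the synthetic generator emulates — and what it does not

The generator plants exactly the structure the analyses assume, so that
recovery can be scored against truth.

*Expression* (`generate_expression()`): cell types are drawn from
entity-specific proportions; counts are negative binomial with
type-programmed means. The reactive profile anchors homeostatic ligands in
stroma (FDC: CXCL13 at mean 25; FRC: CCL19/CCL21/CXCL12; BEC: CXCL12; LEC:
CCL21) and receptors in lymphocytes. The DLBCL profile reduces homeostatic
ligand means to 20% of reactive levels, gives remodeled FRCs high
CXCL9/10/11, puts CXCR3 on cytotoxic T cells and ectopic CXCL13 on a 30%
subset of them (the expressing fraction of such aberrant populations is
typically a minority; 30% is our choice). FL is intermediate: homeostatic
at 60% of reactive, inflammatory at 40% of DLBCL. Dispersion falls from
size 2.0 (rLN) through 1.5 (FL) to 0.8 (DLBCL): interferon-driven
inflammation is transcriptionally patchy, and this overdispersion is part
of the planted heterogeneity that the diffuseness score is designed to
detect. All cell types share a low constitutive program (mean 2) over the
eight "other" registry axes, without which almost no cell pair would
reach four positive axes — as in real tissue, where constitutive
chemokine/receptor expression is broad. Programmed ligand totals satisfy
the entity gradient (homeostatic: rLN > FL > DLBCL; inflammatory:
rLN < FL < DLBCL) by construction, and the suite asserts it.

*Spatial* (`generate_spatial()`): homogeneous Poisson placement over a
1000×1000 μm field; circular follicles (FDC-rich cores, B-cell rings with
T follicular helper admixture) in a T-zone of T cells and FRCs, plus an
optional sinus band (macrophages, lymphatic endothelium); `diffuse = TRUE`
mixes all types uniformly, emulating effaced DLBCL architecture. Marker
intensities are two-component log-normal (negative meanlog 1, positive
meanlog 4, sd 0.5), bimodal as segmented immunofluorescence intensities
are. Transcript counts reuse the entity programs at half scale plus a
20-gene background, so QC, positivity and proximity scoring all operate on
realistic sparsity.

*Survival* (`generate_survival()`): standard-normal signature scores; an
exponential event model whose hazard is multiplied by $e^{\text{effect}}$
below the planted score quantile (default: hazard ratio 3 below the 60th
percentile, baseline median survival 60 months); independent uniform
censoring calibrated by root-finding to the requested censoring fraction.

*Not emulated:* full transcriptomes, batch effects, doublets, segmentation
errors, cell-shape features, and spatial gradients *within* a zone.
Passing tests therefore demonstrate that the algorithms recover the
structure they model — not that real tissue contains no further structure;
in particular the generator cannot validate robustness to segmentation
artifacts or batch integration, which are upstream of this package.

## 7. Problem sizes, determinism and degenerate inputs

The validation suite runs at desk scale, chosen so the planted effects are
comfortably detectable: 2,000 cells per expression cohort (10 seeds per
entity for the diffuseness ordering), up to 25–40 cells per type before
pairing (∼40–60k pair rows per cohort), ∼5,500 cells for structured
spatial recovery and ∼1,000 for each of 10 diffuse layouts, n = 600
subjects (20 replicates) for cutpoint recovery and 200 null cohorts of
n = 100 for type-I calibration of the permutation p.

Every stochastic step takes an explicit seed and is a pure function of
(inputs, seed); the pipeline writes byte-identical artifacts on rerun.
Degenerate inputs have defined behaviour rather than accidents: all-zero
clusters annotate as `unassigned`; a fully merged (single) neighborhood
yields an empty enrichment table; constant intensity vectors are an error
for Otsu; all-identical survival (every subject failing at one time) gives
a zero maxstat statistic and permutation p 1; groups reduced below two
pairs by diffuseness downsampling are skipped with a warning; cells with
zero total counts are a named error in normalization.
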
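---
title: "Inferring c-Fos functional connectivity networks: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring c-Fos functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

## The inference model

c-Fos protein expression peaks roughly 90 minutes after neuronal activity,
so the density of c-Fos-positive cells (cells/mm²) in a brain region is a
snapshot of how active that region recently was. Given one density
measurement per region per animal, *functional connectivity* between two
regions is defined as the covariation of their densities **across animals
within a condition**: if animals with a highly active region A also tend
to have a highly active region B, the two regions are inferred to be
functionally coupled under that condition. This is an inter-animal,
condition-level construct — there is one network per condition, not per
animal — and its sample size is the number of animals, not the number of
cells or regions.

The pipeline is:

1. `correlation_matrix()` — Spearman rank correlation `ρ` and a two-sided
   p-value for each of the C(30, 2) = 435 region pairs.
2. `threshold_network()` — keep pairs with `p < α` (default 0.05,
   uncorrected), both signs; weight the significant *positive* edges by
   the Fisher z-transform `z = atanh(ρ)`.
3. `summarize_network()` — weighted graph metrics and hub ranking on the
   positive z-weight graph.
4. `compare_conditions()` — between-condition contrasts of total and
   node-level connectivity, hemispheric edge counts, positive-correlation
   fractions and per-region densities.

Spearman rather than Pearson correlation is used because densities are
positive, right-skewed, and measured on 8 animals: rank correlation is
invariant to monotone distortions of the density scale and robust to
single extreme animals.

## Exact p-values at small n

With n = 8 animals the null distribution of the Spearman coefficient is
discrete and far from its large-sample approximations, and the pipeline's
edge decisions hinge on p-values near 0.05. We therefore enumerate the
full permutation distribution — all 8! = 40,320 rank assignments — and
report the exact two-sided p-value `P(|ρ_perm| ≥ |ρ_obs|)`. The null
distribution for untied samples depends only on n, so it is computed once
per n and cached; with tied ranks (average ranks, the standard
convention) the observed tie pattern is permuted instead, per pair.
`method = "auto"` uses exact enumeration for n ≤ 9 and the t
approximation `t = ρ√((n−2)/(1−ρ²))` (df = n−2) beyond. Exactness at
n = 8 has a visible consequence: the attainable test levels are discrete,
so the realized false-edge rate at α = 0.05 is ≈ 0.045, not 0.050
(`analysis/06_calibration.R` measures this).

Degenerate inputs are signalled, never imputed: a constant region yields
an undefined correlation (`NA`) with a warning, and such pairs are
excluded from edge sets and from the all-pairs z vector. Missing density
cells are handled by pairwise-complete deletion, with the effective n
recorded per pair. Sample coefficients of exactly ±1 (which occur
regularly at n = 8 under weak coupling) are clamped to ±(1 − 10⁻⁷) before
the z-transform so strengths stay finite; the clamping is warned about.

## Graph metrics: conventions that matter

All metrics follow the Brain Connectivity Toolbox's weighted-undirected
conventions, because small differences in convention change the numbers:

* **Global efficiency** maps each weight to a length `L = 1/w`, computes
  all-pairs shortest paths, and averages `1/d` over ordered pairs with
  **unreachable pairs contributing zero** (kept in the average, not
  dropped). Sparse networks therefore have efficiency well below 1.
* **Clustering** is Onnela's form with weights normalized by the
  **network-wide** maximum (not per-node), `C_i = Σ(ŵŵŵ)^{1/3}/(k(k−1))`,
  zero for nodes of degree < 2.
* **Hub ranking** normalizes nodal strength and degree to the network
  maximum; strength is the primary key, degree the tie-break, atlas order
  the final tie-break, and both full orderings are reported.

Shortest paths are delegated to `igraph::distances()`; both efficiency
and clustering are verified in the test suite against brute-force
Floyd–Warshall and explicit triple-enumeration oracles on hundreds of
random small graphs.

## The synthetic cohort generator

Raw per-animal density tables for this experimental design are typically
not deposited, so the package makes the *generator* a first-class,
tested component rather than shipping a frozen fixture. `generate_cohort()`
draws from a Gaussian copula: a target Spearman matrix is converted to
the latent Pearson scale by the exact bivariate-normal relation
`ρ_P = 2 sin(π ρ_S / 6)`, repaired to the nearest positive-semi-definite
correlation matrix if needed (eigenvalue clipping at 10⁻⁸, diagonal
renormalized; the Frobenius repair distance is reported, and a distance
above 0.1 is an error naming the worst pair), and each margin is pushed
through a log-normal quantile function. Because ranks are untouched by
the marginal transform, the sample Spearman structure converges to the
target regardless of the marginals — the marginal choice (medians 60–150
cells/mm² by anatomical group, CV 0.4) only makes the tables *look* like
c-Fos data (positive, right-skewed) and is configurable.

`study_preset()` encodes a two-condition experiment at the study scale
(n = 8 per condition). The base condition carries a bilateral,
system-structured covariance chosen for anatomical plausibility:
homotopic left/right pairs 0.25, same-hemisphere within-system pairs
0.30, same-hemisphere background 0.15, inter-hemispheric within-system
pairs 0.05. The stimulated condition adds three planted effects — +0.35
to every pair, +0.15 more to inter-hemispheric pairs, +0.40 more to the
LC-L↔LC-R and LC↔DG couplings — capped at |ρ| ≤ 0.85.

Two constraints shaped these defaults, and both are feasibility, not
aesthetics. First, a uniform inter-hemispheric increment on top of a weak
base makes cross-hemisphere correlations exceed within-hemisphere ones,
which is geometrically impossible for a correlation matrix of this shape:
the base *must* carry at least ~0.15 same-hemisphere background for the
planted effects to be realizable. Second, the cap is as high as the joint
structure allows: at 0.85 both conditions' latent matrices are positive
definite without repair, while 0.9 pushes the stimulated condition
outside the feasible set. A side effect worth knowing: the cap compresses
the LC couplings (nominally 0.90–1.15 after effects) down to the same
0.85 as other strong pairs, so the LC's *rank* advantage over, e.g.,
homotopic pairs is modest at n = 8, and hub-rank comparisons between
single simulated cohort pairs are noisy even though the planted LC effect
is real. The mean-connectivity and edge-count signatures are much more
stable across seeds than hub-rank signatures; analyses of hub identity
should aggregate over seeds or use larger n.

What the generator deliberately does **not** emulate: measurement error
in cell counting, between-batch staining effects, non-monotone
region-to-region dependence, and missing data (missingness is supported
by the pipeline but not planted by the preset). Passing recovery tests on
synthetic cohorts therefore demonstrates the *inference machinery* is
correct and calibrated — not that real c-Fos data satisfies the copula
model.

## Statistical design choices

* **No multiple-testing correction by default.** 435 uncorrected tests at
  α = 0.05 imply ≈ 19 false edges per null network; this is the
  field-standard construction for these networks, so it is the default,
  with `adjust = "BH"` available in `threshold_network()` and
  `regional_density_contrast()` for the conservative variant. The
  calibration driver quantifies exactly this burden.
* **Strict inequality** `p < α`, matching the conventional reading of
  "significant at p < 0.05" — relevant because exact permutation
  p-values can equal α or 1 exactly.
* **Both t and Kruskal–Wallis** are reported for every connectivity
  contrast; connectivity-strength vectors are neither normal nor
  independent across pairs, so neither test's nominal p-value should be
  over-read, and reporting both keeps the two conventional surfaces
  available. The t-test uses pooled variance, df = n_a + n_b − 2 (868
  for two complete 30-region conditions).
* **Total connectivity uses all 435 pairs**, unfiltered and of both
  signs: the pooled df of 868 is only consistent with the unfiltered
  vector, and filtering before comparing would bias both conditions
  toward their own thresholds.
* **Hemispheric counts** (per area group: frontal, hippocampal,
  amygdalar, brainstem) count significant edges of either sign with at
  least one endpoint in the group; an edge joining two groups is counted
  in both. This is the only simple rule consistent with intra-hemisphere
  counts that can exceed the C(3,2) = 3 within-group pair limit; it is an
  assumption, and the regions grouped as "other" (PVT, RSP, pRSP)
  contribute only through edges shared with a named group.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
study scale (two conditions × 8 animals × 30 regions), the oracle suites
on 200 random cases each (n ≤ 7 permutation enumeration; ≤ 8-node
graphs), null calibration over 500 simulated cohort pairs, and power
analyses at n up to 500 — a few minutes in total, chosen so the whole
evidence base is recomputed on every run rather than cached.

## Known limitations

* The inference is condition-level: no per-animal networks, no
  hierarchical pooling across conditions.
* Edges are marginal rank correlations; no partial-correlation or
  precision-matrix variant is provided, so indirect coupling through a
  third region appears as an edge.
* The exact permutation machinery is practical up to n ≈ 9–10; beyond
  that the t approximation is used (and is accurate there).
* Negative significant edges participate in edge counts and circle
  diagrams but carry zero weight in all graph metrics, following the
  positive-strength network convention; a signed-graph analysis is out
  of scope.
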
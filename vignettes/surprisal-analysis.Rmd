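---
title: "Surprisal analysis of expression matrices: model, conventions and validation"
author: "surprisalr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis of expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisalr)
```

## The model

Surprisal analysis treats a transcriptome as a thermodynamic-like system: the
observed log expression of gene $i$ in sample $s$ is a maximal-entropy
reference distribution (the *balance state*) deformed by a small number of
*constraints*,

$$
\ln X_i(s) \;=\; G_{i0}\,\lambda_0(s) \;+\; \sum_{\alpha \ge 1} G_{i\alpha}\,\lambda_\alpha(s).
$$

The factorization is computed as the economy-size singular value
decomposition of the $N \times N_s$ matrix $\mathbf{Y}$ of natural-log FPKM
values: $G_{i\alpha} = U_{i\alpha}$ and
$\lambda_\alpha(s) = \omega_\alpha V_{s\alpha}$. Component $\alpha = 0$
carries the largest singular value and is the balance state: its per-sample
multiplier $\lambda_0(s)$ is nearly constant, and its per-gene term
$G_{i0}\bar\lambda_0$ is the gene's prior thermodynamic weight (its negation
is a free energy: large weight = stable, highly expressed everywhere).
Components $\alpha \ge 1$ quantify coordinated deviations; the sign of
$\lambda_\alpha(s)$ partitions samples into the two phenotypes of that
constraint. Keeping all $N_s$ terms reconstructs $\mathbf{Y}$ exactly, which
the package asserts to $10^{-8}$.

Why the log scale matters: the SVD of raw ln FPKM (no mean-centering) makes
the shared expression profile the dominant component. This is a deliberate
contrast with the K-means stage below, which follows the standard practice of
gene-level mean-centering and therefore discards exactly the balance
information that surprisal analysis keeps.

### Conventions fixed by this package

An SVD determines each component only up to a joint sign flip of
$(G_{\cdot\alpha}, \lambda_\alpha)$. Three conventions are applied:

* `orient_study()` — balance multiplier positive on average; constraint 1
  positive over liquid-grown samples; constraint 2 positive over light-grown
  samples. Under this orientation, genes with $G_{i1} > 0$ are overexpressed
  in liquid and underexpressed on agar, and analogously for light/dark.
* `orient_by_anchor_gene()` — in repeated subsampling the per-draw SVD signs
  are arbitrary; they are reattributed by requiring a chosen anchor gene
  (by default the strongest-weight gene of the component in a full-data run)
  to keep a fixed sign.
* $\lambda_\alpha(s)$ is defined as $\omega_\alpha$ times the $s$-th
  component of the $\alpha$-th right singular vector; the scalar in the
  balance term is the across-sample mean $\bar\lambda_0$, since
  $\lambda_0(s)$ is only approximately constant. Per-sample values are also
  exposed.

Degenerate (tied) singular values are returned in factorization order; this
cannot occur on continuous data and is only guarded against crashing.

## Preprocessing

The study configuration reads a gene-by-sample FPKM matrix with sample
metadata (medium, light, series, strain, lab) and applies, in order:

1. `filter_low_expression()` — drop genes whose *raw* mean FPKM over the
   reference group (the agar-grown samples, both light and dark) is below
   1 FPKM. Filtering precedes flooring because flooring would raise the means
   it is computed from. The reference group is configurable; "all samples" is
   the neutral default.
2. `apply_floor()` — replace values below 0.01 FPKM by 0.01 FPKM so
   logarithms are finite.
3. `to_log()` — natural log.

Duplicate gene ids, negative values and samples without metadata are fatal
errors, never silently repaired.

## Phenotype statistics

For each constraint the package reports the per-group sign tallies (exact
zeros are their own category), the discordant samples (minority sign within
a group), the overall spread $\max_s \lambda_\alpha(s) - \min_s
\lambda_\alpha(s)$, the inter-group gap, and a two-sided Wilcoxon rank-sum
test between the two groups. The spread over *all* samples is the primary
range statistic, mirroring how the balance-state range is quoted; the gap is
reported alongside because the phrasing "difference between the range of
positive and negative values" admits both readings. The Wilcoxon test uses
the exact null distribution for combined $n \le 20$ without ties and the
normal approximation with continuity correction otherwise. No
multiple-testing correction is applied across constraints: per-constraint
p-values are reported raw, as is conventional for this analysis.

## Pathway set ratios

For a pathway $J$ and constraint $\alpha$, member genes are split by the
sign of $G_{i\alpha}$ and their **squared** weights summed:
$P^J_\alpha = \sum_{G_{i\alpha} > 0} G_{i\alpha}^2$,
$N^J_\alpha = \sum_{G_{i\alpha} < 0} G_{i\alpha}^2$, and the set ratio is
$SR_J = P^J_\alpha / N^J_\alpha$. Because each $G$ column is a unit vector,
$P + N$ is the pathway's share of 1 and pathway scores over any disjoint
cover of the genes sum to 1 — the conservation property the tests assert.
Squaring is the consequential design choice here: only squared unit-vector
components produce the $10^{-4}$–$10^{-6}$ magnitudes that per-pathway
weights of a ~13k-gene decomposition must have, and the ratio is then
invariant under the overall scale of the component.

Ranking: high $SR$ marks enrichment in the positively-signed phenotype, low
$SR$ in the negatively-signed one. Sets whose member weights are all of one
sign have no finite ratio; they are placed at the extreme of the
corresponding ranking and ordered by $P$ (or $N$) — an all-positive set is
maximally enriched in the positive phenotype. Ties break lexicographically
by pathway id; pathways with all-zero member weights are dropped with a
message. For the balance state, where orientation makes one sign dominant,
ranking is by $\max(P, N)$. Pathways are restricted to the analyzed gene
universe; those with fewer than 10 remaining members are dropped (the
configurable `min_size`). A gene may belong to several pathways and
contributes to each.

## Top-gene lists

Genes are ranked by $G_{i\alpha}$; the $n$ largest and $n$ smallest (default
100) are the per-phenotype "top-contributing" lists — a ranking notion, not
a statistical test, and deliberately named to avoid conflation with
count-model differential expression. Ties break by gene id so lists are
reproducible.

## Randomization

Robustness to the unbalanced design is assessed by re-running the whole
decomposition on stratified subsamples: 6 AL, 3 AD and 3 LL samples drawn
without replacement per draw, plus both LD samples always (they are too few
to subsample), giving 14 of the 38 samples; 1000 draws by default. Each draw
is re-decomposed from scratch (not projected from the full decomposition),
sign-reattributed via the anchor genes, tested for Wilcoxon separation of
both constraints at 0.05, and scored per pathway. Aggregation reports
per-sample means and SDs of $\lambda_{0..2}$ over the draws containing the
sample, per-pathway mean/SD of $P$, $N$ and $SR$, and the fraction of draws
whose separations pass. A master seed spawns one substream seed per draw, so
any individual draw is reproducible in isolation; identical subsets may
recur by chance and are not deduplicated. Gene filtering is not recomputed
per draw — the analyzed gene universe is fixed upstream.

## K-means cross-validation

The comparison clustering follows the standard statistical route:
ln-transform, gene-level mean-centering, K-means with Pearson-correlation
distance, $k$ chosen by the figure of merit. Distances use
$1 - \mathrm{cor}$; internally rows are centered and scaled to unit norm so
the correlation is a dot product, and the centroid update is the normalized
mean of member unit profiles. With that update the total-distance objective
is provably non-increasing and the implementation asserts it at every
iteration. The best of `n_init = 10` random restarts is kept; an empty
cluster is re-seeded from the gene least correlated with its centroid; row
scaling cannot move a gene (correlation is scale-free per row). The figure
of merit is the leave-one-sample-out scheme: cluster on all but one sample,
measure the root-mean-square deviation of the left-out column from its
cluster means, adjust by $\sqrt{(N-k)/N}$, sum over left-out samples; the
recommended $k$ is the smallest whose relative improvement toward $k+1$
falls below 0.1. Clusters are labelled automatically with the phenotype
(agar/liquid/dark/light) whose samples have the highest centroid mean —
replacing the by-eye assignment a GUI tool invites — and `overlap_table()`
cross-tabulates the surprisal top-$n$ lists against the clusters, reporting
both per-phenotype and pooled matched fractions (the published claim is
ambiguous between the two, so both are computed).

## The synthetic-data generator

No raw data ships with the package; the generator produces matrices with
*known* surprisal structure so that every stage can be validated against a
planted truth:

$$\ln X = G_0\lambda_0 + G_1\lambda_1 + G_2\lambda_2 + \varepsilon,
\qquad \varepsilon \sim \mathcal{N}(0, \sigma^2).$$

Choices, and why:

* **Planted factors are an exact SVD basis.** Raw weight vectors (uniform
  positive baseline for $G_0$; standard normal background plus strong
  one-signed marker blocks for $G_1$, $G_2$) are QR-orthonormalized, and the
  multiplier rows are built exactly mean-zero and mutually orthogonal, with
  only the balance jitter projected into the orthocomplement. Consequently
  at $\sigma = 0$ the matrix has rank 3 and the decomposition recovers the
  truth to machine precision — the oracle the tests rely on. Recovery is
  always measured against the post-orthonormalization truth.
* **Multiplier geometry mirrors the study conditions.** Defaults: balance
  spread 41 ln units; constraint spreads 152 (medium) and 133 (light);
  38 samples in the 23/5/8/2 AL/AD/LL/LD design; noise sd 0.1 — group
  separations far above noise, as in the data the method targets. The
  default gene count is 2000 for speed; `synthetic_study_config()` scales to
  12774 genes, plants the two discordant samples the full-size analysis
  exhibits (one agar sample with a slightly positive $\lambda_1$, one light
  sample with a slightly negative $\lambda_2$; the non-discordant
  coordinates absorb exact closed-form corrections so orthogonality is
  preserved), and raises the balance level to 3 ln units. The balance level
  must grow as the gene count shrinks: the balance component's norm scales
  like $\bar\lambda_0\sqrt{N_s}$ while the constraint norms are fixed by
  their spreads, and the generator refuses configurations in which the
  balance would not dominate.
* **Phenotype markers and pathway planting.** Each phenotype gets a block of
  marker genes (default 120; 300 at study scale) with strong one-signed
  weights in its constraint; enriched pathways draw 80% of their members
  from those markers, the rest at random; non-enriched pathways are random.
  Markers model the hundreds of genes a real condition program regulates,
  and make the top-gene, enrichment and cluster-overlap stages testable.
* **Post-filter universe.** The study-scale preset guarantees every gene
  passes the 1-FPKM agar-mean filter (`ensure_filter_pass`): any straggler
  FPKM row is lifted by a per-gene constant on the ln scale — a pure
  balance-direction perturbation that leaves the constraints untouched.
  This encodes the fact that the emulated gene universe is defined *after*
  filtering.

What the generator does **not** emulate: count noise and overdispersion
(noise is Gaussian on the ln scale), gene-gene correlation beyond the
planted factors, batch effects beyond the lab/strain labels, and any
read-level structure. Passing tests therefore demonstrate that the pipeline
recovers planted low-rank structure under Gaussian noise at realistic
scales — not that real data satisfies the model.

## Problem sizes used in validation

Unit and property tests run on matrices from 3×2 up to 2000×38; the
end-to-end checks run the full 12774×38 study-scale emulation (decomposition,
ranges, partitions, K-means with 10 restarts) plus 20 seeded replicates of
the default configuration for recovery statistics, and randomization checks
with up to 1000 stratified draws. These sizes were chosen so the complete
validation runs comfortably on a laptop while still exercising the full
study geometry.

## Known limitations

* The balance/constraint decomposition is a linear model on the ln scale;
  strongly nonlinear condition effects would spread across several
  components.
* Set ratios compare squared-weight masses, not membership counts; a
  pathway with one enormous weight can outrank a coherently shifted one.
* The Wilcoxon test treats samples as exchangeable within groups; batch
  structure (two labs, two strains) is visible in constraint 3 and is
  reported but deliberately not interpreted.
* With only two LD samples the light constraint leans heavily on the AD
  series; the randomization module quantifies, but cannot remove, that
  sensitivity.

```{r session, eval = FALSE}
sessionInfo()
```
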
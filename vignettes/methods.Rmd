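---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytofl)
```

# Scope

`cytofl` analyses multi-sample, multi-batch mass cytometry (CyTOF) cohorts
of B-cell lymphoma and reactive lymph node (rLN) samples. The pipeline runs
from raw per-cell marker intensities to a cohort report: spillover
compensation, arcsinh transformation, control-anchored batch normalization,
graph-based consensus clustering, gap-statistic metaclustering, light-chain
clonality calls and tumor typing, Shannon-entropy heterogeneity statistics,
and an exact probabilistic co-occurrence network over cell populations. A
synthetic cohort generator with planted ground truth makes every stage
testable without patient data.

# Preprocessing

**Spillover compensation.** Metal-isotope channels leak a small fraction of
signal into neighboring masses. With spillover matrix $S$ ($S_{ij}$ = the
fraction of channel $i$ signal read in channel $j$, unit diagonal), the
observed row $y$ satisfies $y = x S$ for true abundances $x \ge 0$.
Ordinary inversion can produce negative abundances, which are physical
nonsense; `compensate_nnls()` instead solves
$\hat x = \arg\min_{x \ge 0} \lVert S^\top x - y \rVert_2$ per cell.
Cells whose unconstrained solution is already nonnegative are handled by a
single matrix inversion; the remainder go through a Lawson–Hanson
active-set solver (tolerance $10^{-10}$), so clamped solutions satisfy the
KKT conditions. Matrices with condition number above $10^8$ are rejected by
name. Compensation acts on the raw scale, where spillover is linear.

**Arcsinh transform.** `arcsinh_transform()` applies
$z = \operatorname{asinh}(a\,x)$ elementwise with $a = 0.2$ (cofactor 5,
the community standard for CyTOF). The parameterization with offset
$b = 0$ is read as $\operatorname{asinh}(a \cdot x)$; a literal
$\operatorname{asinh}(a + b x)$ with $b = 0$ would be constant and is
rejected as a transcription artifact. The transform is monotone, so
per-channel rank order is preserved.

**Batch normalization.** Each acquisition batch includes an aliquot of one
pooled rLN-like control. For channel $c$ and batch $b$, the factor is
$f_{bc} = \mathrm{med}_{bc} / \min_{b'} \mathrm{med}_{b'c}$, where
$\mathrm{med}_{bc}$ is the control median — every channel is anchored to
its weakest batch, so $f \ge 1$ with per-channel minimum exactly 1, and
dividing by $f$ equalizes control medians across batches.

Factors are estimated and applied on the **raw** scale by default. The
pipeline order is compensate → normalize → transform, which makes
normalization exactly inverse to a multiplicative acquisition drift: a
planted per-channel factor $g$ is recovered as $\hat f \approx g$ and
divided out before the (nonlinear) arcsinh step. Estimating on the arcsinh
scale is supported — `estimate_batch_factors()` operates on whatever scale
its input carries and `apply_batch_normalization()` refuses a scale
mismatch — but a multiplicative raw-scale drift does not translate into a
constant arcsinh-scale ratio, so raw is the default.

A caveat worth knowing: the median of a channel whose control-mixture
median falls *between* expression modes (flat density) is an intrinsically
noisy estimator; its sampling error is roughly $1.25\,\sigma / \sqrt{n}$
only where the density is unimodal. This is why the control aliquot should
be large (the generator default mirrors this; the batch-recovery tests use
8000 control cells, putting estimator noise near 1%) and why factor
recovery is asserted on a unimodal channel.

**Combined light chain (KL).** Clustering replaces the kappa and lambda
channels with their per-cell maximum (`synthesize_kl()`): a clonal
population is then uniformly light-chain-high regardless of which chain it
expresses, so kappa and lambda clones of the same phenotype co-cluster.
The original channels are retained for clonality analysis.

# Consensus clustering

Cells are clustered PhenoGraph-style: exact Euclidean k-nearest-neighbor
search (ties broken by cell index), an undirected graph over (cell, kNN)
pairs weighted by the Jaccard overlap of the two cells' neighbor sets, and
Louvain modularity maximization (via igraph, seeded for determinism). The
cohort-scale default is `k_neighbors = 100`; on small synthetic cohorts the
pipeline caps k at a tenth of the cell count with a warning, since a
neighborhood larger than the structures being sought destroys them.

Louvain is randomized, so `consensus_cluster()` runs it $R = 25$ times
(seeds `seed .. seed+R-1`), computes all pairwise adjusted Rand index
(ARI) and normalized mutual information (NMI) scores, and selects the run
with the highest mean off-diagonal ARI, ties broken by mean NMI, then by
lowest run index. The NMI normalization variant is not standardized; the
default divides by $\sqrt{H(u) H(v)}$, with `max` and `arithmetic`
available. Conventions for degenerate partitions: one single-cluster
partition scores NMI 0, both single-cluster score 1.

Rare populations are pruned per sample: cells in clusters holding less
than 1% of their sample's cells are dropped (threshold inclusive — exactly
1% is retained). Fractions are per sample, so a cluster can survive in one
sample and be pruned in another.

One stability caveat: igraph's Louvain sweeps vertices in id order, so
clustering after a permutation of cells is near-identical (ARI ≥ 0.99 on
separated data) but not bit-identical. Determinism for a *fixed* input and
seed is exact.

# Metaclustering and the gap statistic

Fine clusters are collapsed by hierarchically clustering their median
marker profiles (Ward linkage on Euclidean distance; `complete`/`average`
configurable). The number of metaclusters is chosen by the gap statistic:
for each $k$, $\mathrm{Gap}(k) = \tfrac1B \sum_b \log W^*_{kb} - \log W_k$,
where $W_k$ is the pooled within-cluster dispersion of the $k$-cut and the
$B = 50$ references are drawn uniformly over the per-feature ranges
(Tibshirani's simpler reference; a PCA-rotated box is deliberately not
implemented — profile matrices here are small and well-conditioned).
$\mathrm{se}_k = \mathrm{sd}_b(\log W^*_{kb})\sqrt{1 + 1/B}$, and the
chosen $k$ is the smallest with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - \mathrm{se}_{k+1}$ (the 1-SE
rule; the original report does not state its rule, so the standard one is
used).

**MC-A / MC-B annotation.** The two recurrent tumor phenotypes are
identified from signature contrasts: the germinal-center-like type
expresses IgG/HLA-DR/CD22, the memory-like type IgM/CD79B/CD24/CD44. Each
fine cluster is scored by the difference of its mean median expression
over the two signatures; a metacluster is named MC-A (MC-B) when its
strongest member cluster scores at least `margin = 2` above (below) zero
on the arcsinh scale. The strongest member rather than the metacluster
average is used because MC-A legitimately subsumes normal germinal-center
clusters of intermediate score. At most one metacluster receives each
name. The margin of 2 sits between the clonal templates' contrasts (≈ ±3.2)
and every other template's (≤ 1.9 in magnitude) with sampling noise on
medians well under 0.1 at the default cell counts.

**Marker ranking.** Panel-reduction scores each marker by the
Kruskal–Wallis H of its per-sample clonal-cell median across tumor types
and reports the cumulative normalized share of total score in rank order.
The published "98% of information content with 26 of 39 markers" uses an
unspecified measure; the analogous cumulative-share curve is reported
without claiming numeric equivalence.

# Entropy statistics

Both statistics use the natural logarithm (units: nats).

**Inter-sample (mixing) entropy** (`intersample_entropy()`): per cell,
$-\sum_m p_m \ln p_m$ where $p_m$ is the fraction of sample $m$ among the
cell's $K$ nearest neighbors ($K = n_\text{samples} - 1$ by default,
mirroring cohort-scale usage; self excluded to avoid a constant own-sample
bias). Computed in full marker space (whether the original was computed in
embedding space is unstated; full space avoids an extra stochastic step).

**Intratumoral entropy** (`intratumoral_entropy()`): per sample,
$-\sum_i p_i \ln p_i$ over the proportions of each abnormal (monotypic)
cluster among the sample's abnormal cells, with $0 \ln 0 \equiv 0$. A
tumor whose clonal cells occupy a single cluster scores exactly 0; $k$
equal subclones score $\ln k$.

# Clonality and tumor typing

Per (sample, cluster), kappa- and lambda-positive cells are counted
(positivity: arcsinh intensity > 1, i.e. raw ≈ 5.9 at cofactor 5 — well
above the truncated-noise mode and below every positive-population mode;
a median-intensity ratio is available behind a flag). The kappa:lambda
ratio calls the cluster monotypic-kappa above 7, monotypic-lambda below
0.3, and polytypic on the closed interval $[0.3, 7]$ (inclusive bounds
read conservatively as polytypic). A zero denominator with positive
numerator yields an infinite ratio and the corresponding monotypic call —
no pseudocount, since a pseudocount would shift genuine ratios near the
boundary. Clusters of ≥ 50 cells with no positive cells on either chain
are reported "indeterminate" rather than errored.

Monotypic clusters that map to normal phenotype groups are flagged `Ab`
(aberrant counterparts of normal phenotypes); the flagged chain is checked
against the sample's dominant monotypic chain and disagreement warns.

**Typing.** A sample's clonal B-cells are the cells of its monotypic
clusters. Under the `most-abundant` rule the sample takes type A (B) when
its most abundant metacluster among clonal cells is MC-A (MC-B), else NOS;
under `majority-50` the dominant metacluster must additionally exceed 50%
of clonal cells. Samples with no monotypic cluster are `rLN-like`. Ties
for the dominant metacluster give NOS (deterministic and conservative).
Both rules are computed and reported side by side; the original account
uses both formulations in different places, so neither is privileged.

# Co-occurrence model

Populations present in more than 1% of a sample's cells (strict
inequality; an absolute-count mode with ≥ is available) define a binary
samples × populations matrix. For each pair with margins $N_1, N_2$ of $N$
samples, the overlap under independence is hypergeometric:
$P(j) = \binom{N_1}{j}\binom{N-N_1}{N_2-j} / \binom{N}{N_2}$ on
$j \in [\max(0, N_1{+}N_2{-}N),\ \min(N_1, N_2)]$. Tail probabilities
$p_{\ge}$ and $p_{\le}$ at the observed overlap call significant positive
and negative associations at $\alpha = 0.05$ per tail, with **no**
multiplicity adjustment (matching the source method's validated regime).
Pairs with expected overlap below 1 are flagged `low_expectation` rather
than dropped, preserving auditability. Network edges carry weight
$e^{s}$ with $s = (j_\text{obs} - E[J])/\mathrm{sd}(J)$ — the exponential
maps negative scores onto small positive weights as force-directed layout
engines require; the score definition is this package's choice since the
original does not define one.

Mutual exclusivity of two populations is additionally tested by Pearson
chi-square (1 df, no continuity correction) on the 2×2 presence table.

Samples are clustered by composition with Ward linkage on
$\sqrt{\mathrm{JSD}}$, where
$\mathrm{JSD}(P,Q) = H(M) - (H(P)+H(Q))/2$, $M = (P+Q)/2$, natural log
(maximum $\ln 2$ at disjoint support). The square root makes the quantity
a metric before Ward aggregation.

# Synthetic cohorts: what they emulate, and what they do not

`simulate_cohort()` draws each cell from a population template — an
independent Gaussian on the arcsinh scale (means high ≈ 4, mid ≈ 2,
baseline 0.5; sd 0.35), mapped to the raw scale by $\sinh(z)/a$ and
truncated at zero, then multiplied by its batch's per-channel drift factor
and mixed through the spillover matrix. Light chains are drawn per
template clonality: polytypic templates assign each cell kappa with
probability 0.6, monotypic templates put all cells on one chain; the
expressed chain reads ≈ 4, the other ≈ 0.3.

The defaults state the world the validation tests assume. Four normal
templates (naive, pre-switch memory, germinal center,
plasmablast/plasma cell) carry canonical marker patterns; `clonalA`
(IgG+/HLA-DR+/CD22+) and `clonalB` (IgM+/CD79B+/CD24+/CD44+) mirror the
qualitative contrasts of the two recurrent lymphoma phenotypes; three
divergent clones are separated on padding channels. All template means are
invented — the published study does not report marker-level distributions
— and are labelled synthetic. Mean contrasts are at least 4 sd, which is
what "well-separated" means throughout the tests. The demonstration cohort
(`demo_cohort_config()`) plants 4 A-like, 4 B-like and 4 divergent samples
over 2 batches with drift factors ramping 1.1–1.6 and 5% sparse spillover;
its composition puts MC-A-and-MC-C together in 8 of 12 samples and MC-B in
a disjoint 4, margins at which the exact model flags the planted positive
and negative associations at $\alpha = 0.05$.

A green end-to-end test therefore establishes that the pipeline recovers
*strongly planted, well-separated* structure through realistic batch and
spillover nuisance — not that it resolves subtle phenotypic gradients,
doublets, acquisition-time drift within a batch, or the continuous
variation of real tumors, none of which the generator emulates.

# Numerical choices and degenerate inputs

- NNLS tolerance $10^{-10}$; condition-number cutoff $10^8$; deterministic.
- Median: R's default (mean of the central pair at even n).
- kNN ties: broken by cell index after a stable sort.
- Consensus ties: mean NMI, then lowest run index.
- Gap statistic needs ≥ 3 cluster profiles; below that the cluster count
  is used directly.
- Zero-entropy guards: $0 \ln 0 = 0$ everywhere; compositions must sum to
  1 within $10^{-9}$.
- Chi-square with a zero margin errors (the statistic is undefined);
  degenerate hypergeometric margins ($N_1 = N$) give $p_{\le} = p_{\ge} = 1$.
- All randomness flows from one root seed through fixed per-stage offsets;
  RNG state is saved and restored around every seeded operation, so
  library calls never perturb a caller's stream.

# Known limitations

- FCS ingestion is not implemented (no flow IO library in the supported
  stack); cohorts move as per-sample CSV plus a JSON manifest.
- The marker-ranking "information share" is a Kruskal–Wallis proxy for an
  unspecified published measure; treat cross-study numeric comparison of
  shares as unsupported.
- Louvain order-dependence (above) makes permutation invariance
  approximate.
- UMAP/t-SNE embeddings are out of scope; entropy and clustering operate
  in marker space.
- Survival association of types and entropy is out of scope (routine
  off-the-shelf modelling).
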
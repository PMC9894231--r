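---
title: "Methods: fused phenotypic networks and compound activity mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused phenotypic networks and compound activity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snfmap)
```

## The problem

Natural-product fraction libraries are mixtures: each chromatographic
fraction of a microbial extract contains many metabolites, usually with at
most one or a few driving any observable bioactivity. Phenotypic screening
platforms read out a perturbation's effect on cells — here a gene-signature
panel (14 dynamic reporter genes, "FUSION"-style) and an image-based
cytological-profiling panel (251 features, "CP"-style) — but each platform
is blind to mechanisms its readout does not capture. `snfmap` implements an
integration strategy: fuse the two platforms' similarity structures into one
network, cluster it, benchmark how well the fused network preserves known
mechanism-of-action (MOA) classes, and then score untargeted-metabolomics
features by how coherently the fractions containing them behave in the fused
network.

## Normalization and quiet perturbagens

Raw well-level profiles are Z-scored per feature against the control wells of
their normalization group (per plate when plate ids exist, otherwise
globally): subtract the control mean, divide by the control *sample* standard
deviation (n − 1 denominator; the convention matters for the hand-computable
oracles in the test suite). Replicate wells of a perturbagen are averaged
*after* Z-scoring — one signature per perturbagen. A feature whose controls
are constant carries no information and its Z is set to 0 with a warning
rather than propagating an infinity.

A perturbagen is **quiet** when every |Z| is strictly below `tau` (default
0.5). Quiet perturbagens are flagged, and flags from two platforms can be
intersected, but they are *not* removed before fusion: quietness in one
platform is precisely the situation fusion is meant to rescue.

## The fused network

For each platform the perturbagen-by-perturbagen distance matrix is either
squared Euclidean (the `dist2` convention) or the Pearson distance
(1 − r)/2. Distances become affinities through a locally scaled exponential
kernel

$$W(i,j) = \exp\!\left(-\frac{D(i,j)}{\mu\,\varepsilon(i,j)}\right),
\qquad
\varepsilon(i,j) = \frac{\bar d_k(i) + \bar d_k(j) + D(i,j)}{3},$$

where $\bar d_k(i)$ is the mean distance from $i$ to its $k$ nearest
neighbours and $\mu = 0.5$. The kernel is scale invariant, so the two
platforms' very different feature counts and units drop out.

Fusion is iterative cross-network diffusion: each platform's full-kernel
transition matrix $P_v$ (off-diagonal row sums 1/2, diagonal 1/2) is
repeatedly replaced by $S_v \bar P_{-v} S_v^\top$, where $S_v$ is the
platform's sparse k-nearest-neighbour kernel and $\bar P_{-v}$ the mean of
the other platforms' transition matrices, then symmetrized and renormalized;
after $t = 20$ rounds the fused network is the mean of the $P_v$. Pairs
similar in *both* platforms reinforce each other; pairs similar in only one
platform survive if the neighbourhood structure supports them.

Because a single $k$ bakes in one neighbourhood scale, the pipeline sweeps
$k = 2, \dots, \lfloor n/2 \rfloor$ (for even $n$ this yields $n/2 - 1$
fused matrices), range-normalizes each fused matrix by its maximum
off-diagonal entry, and averages element-wise into the aggregate matrix
`w_agg` with off-diagonal values in (0, 1]. The same sweep applied to each
platform alone (self-diffusion — the two-network update with both inputs
equal collapses to it exactly, which the tests exploit as a fixed-point
oracle) yields per-platform aggregate matrices on the same diffusion scale,
kept for edge attribution.

Downstream similarity is computed on the log10 of `w_agg` (entries floored
at 1e−12 against kernel underflow): either row-wise Euclidean distance or
row-wise Pearson correlation between perturbagen similarity profiles.

## Clustering

Affinity propagation (APC) clusters the fused similarities by message
passing. It is attractive here because it chooses the number of clusters
itself and names an exemplar per cluster, and because it can be made fully
deterministic: this implementation adds no jitter and breaks all ties by
lowest index, so repeated runs are bit-identical. The hierarchy re-clusters
the exemplars on the restricted similarity sub-matrix until the cluster
count stops decreasing. The preference defaults to the median off-diagonal
similarity and may be set per level.

Two numerical caveats are documented rather than hidden. First, for an
isolated two-member cluster the exemplar-selection criterion
$R(k,k) + A(k,k)$ converges to exactly zero, so which of the two points is
called exemplar (or whether a degenerate pair splits) is decided by
floating-point dust in *any* implementation; reference implementations
typically add noise to break these ties. The test suite therefore compares
clusterings against the reference after applying the package's lowest-index
tie rule to both sides, and validation geometries use clusters of three or
more points. Second, non-convergence within `max_iter` is reported in the
result rather than raised.

Each member-to-exemplar edge is attributed to the platforms by
$r = \log_{10}(\mathrm{Aff}_A / \mathrm{Aff}_B)$ computed from the
per-platform aggregate matrices: $r \le -0.5$ is labelled as supported by
platform A, $r \ge 0.5$ by platform B, and everything in between by both.
This orientation follows the source analysis as printed even though the
sign convention may look inverted (a large A:B ratio flags B); a `swap`
switch inverts only the labels, never the ratio.

## MOA benchmarking

For every annotated target class with at least five members, the in-class
sample (all pairwise values among members) is compared with the
out-of-class sample (members × members of other classes) by a one-sided
two-sample Kolmogorov–Smirnov test — in-class distances stochastically
smaller, or in-class correlations stochastically larger. Exact p-values (the
Smirnov permutation null) are used whenever `stats::ks.test` can compute
them; the suite verifies exact agreement with brute-force enumeration over
all $\binom{m+n}{m}$ assignments for small samples. Cluster enrichment uses
the upper-tail hypergeometric test with unannotated perturbagens counted in
the population but in no class, Bonferroni-corrected by the number of
classes tested. The k-means comparison (k = 30, fixed seed, 25 restarts,
Euclidean on Z-scores) reproduces the per-platform concordance analysis.

## Metabolomics, baskets, and the SNF score

Replicate-level MS features (m/z, retention time, optional collision cross
section, intensity) are collapsed per sample: observations are processed in
ascending m/z and greedily grouped within tolerances (defaults 0.01 Th,
0.2 min, 5% CCS), one observation per replicate per group, and only groups
seen in ≥ 2 of 3 replicates survive. Sample-level consensus features are
then **basketed** across the library by single linkage within the same
tolerances — a deliberate choice: chains merge, which mirrors how adducts
and in-source fragments drift, and the ascending-m/z processing order makes
the result deterministic. The defaults were chosen to merge features a few
mDa and a few hundredths of a minute apart, the scale of the instrument
drift the replicate design anticipates, and are fully configurable.

Each basket gets five descriptors. The **SNF score** is the mean
off-diagonal entry of `w_agg` restricted to the fractions containing the
basket (a basket in two fractions scores their single pairwise similarity;
singletons score 0 by convention so percentile ranks stay total). The
per-platform **cluster scores** are the analogous means over the platforms'
Pearson-correlation matrices of Z-profiles. The per-platform **activity
scores** are the Euclidean norm of the element-wise mean Z-fingerprint of
the containing fractions divided by $\sqrt{\#\text{features}}$ — a
reconstruction in the compound-activity-mapping lineage, since the source
names but does not define the formula; it is 0 for silent fingerprints and
1 for a consistent all-|Z|=1 fingerprint.

Bioactive candidates are selected either strictly above an absolute score
threshold (0.06 for map building) or by percentile: the nearest-rank
percentile marks the cutoff and baskets strictly above it are retained,
with ties spanning the boundary kept — so 100 distinct scores at the 95th
percentile keep exactly 5, while a fully tied score vector keeps all. The
**Compound Activity Map** is the bipartite graph of extracts and surviving
baskets; extracts with no surviving basket are dropped, and an extract's
score is the mean of its incident baskets' scores (an aggregation choice
this package documents, as the source colors extracts without defining
one).

## The synthetic screen

`simulate_screen()` generates the study conditions every stage is tested
under: 10 planted MOA classes × 8 reference compounds, 80 unannotated
noise compounds, and 60 fractions, with platform feature counts 14 and 251.
Each class has a mean Z-fingerprint of Euclidean norm `d = 2` per platform,
zeroed where the class is invisible — visibility cycles through
both/A-only/B-only, so fusion must rescue classes one platform cannot see.
Members add i.i.d. Gaussian noise with sd $1/\sqrt{3} \approx 0.577$: the
profiles emulate triplicate-averaged Z-scores, and averaging three
unit-variance Z replicates leaves exactly this residual sd. Five classes
drive bioactivity: one bioactive compound each, planted in four disjoint
fractions, alongside 3–10 inert compounds drawn from a shared pool of 40;
bioactive fractions carry their class's fingerprint, inert fractions pure
noise. `simulate_metabolome()` emits each compound's feature in three
replicates with m/z and RT jitter, 10% per-replicate dropout (creating the
1-of-3 features the consensus rule must remove), and three sample-unique
decoy features per fraction (which basket as singletons, emulating the
large single-occurrence fraction seen in real libraries). Compound m/z
values sit on a jittered grid spaced 0.7 Th so distinct compounds never
collide within tolerance — the generator tests recovery, not mass accuracy.

What the generator does *not* emulate: correlated (non-spherical) noise,
dose–response structure, adduct/fragment families sharing retention time,
intensity-dependent dropout, plate effects beyond control normalization.
Passing tests therefore demonstrate the pipeline's logic and numerics, not
instrument-level realism.

## Problem sizes and determinism

The validation suite runs the full pipeline at the default screen size
(220 perturbagens, k swept 2…110, t = 20) across 20 seeds, plus
property checks on small random instances (fixed-point and normalization on
n ≤ 20; clustering parity on n ≤ 12 against an independent reference;
exhaustive KS enumeration up to 10 pooled values; hypergeometric summation
up to N = 60; 100 random baskets against a brute-force score). All
randomness flows through explicit seeds; the clustering itself uses none.

## Known limitations

* The SNF score is intensity-blind: a bioactive metabolite present below
  its effective concentration in some fractions dilutes its own score, and
  co-expressed active/inactive metabolites are indistinguishable.
* Only two input platforms are exercised, though the diffusion update
  generalizes.
* Exact KS p-values are unavailable in the presence of ties (the asymptotic
  one-sided approximation is used there, as in `stats::ks.test`).
* Affinity propagation's two-member-cluster degeneracy (above) means
  exemplar identity inside tied pairs is conventional.
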
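---
title: "Methods: bipartite plankton co-occurrence networks and their stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite plankton co-occurrence networks and their stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pznet)
```

## The problem

Phytoplankton and the zooplankton that graze on them form the base of
marine food webs. Because the two guilds are sampled with different nets
(and zooplankton with nets of different mesh sizes, here a "smaller"
~160 µm and a "bigger" ~500 µm fraction), the natural data structure is a
set of sample × species density tables (ind/L) plus a taxonomy and a
sample × environmental-factor table. `pznet` infers signed *bipartite*
co-occurrence networks between guilds (or between zooplankton size
fractions), and quantifies their topology, non-randomness, stability and
environmental associations. Everything is driven through a synthetic
community generator with known ground truth, so each stage is testable
without field data.

## Data model and the size-fraction intersection

`abundance_table` holds a nonnegative density matrix with per-species
guild / size-fraction / taxon-group annotations and per-sample site
labels. Before any cross-fraction comparison, `intersect_size_fractions()`
restricts both zooplankton tables to the species caught by both nets;
otherwise differences between the fraction networks would partly reflect
inventory differences rather than association differences. Species names
are matched by exact string equality after whitespace/case normalization —
taxonomic name resolution is out of scope. Missing environmental values
are imputed by the per-site median (falling back to the global median),
a robust, site-local choice.

## Compositional correlation (SparCC)

Plankton densities behave compositionally: closure (per-sample totals) can
induce spurious negative correlations among proportions. The network
backbone is therefore a sparse compositional correlation estimate. With
fractions $x_i$ the log-ratio variances
$t_{ij} = \mathrm{var}\,\log(x_i/x_j)$ depend only on relative abundances.
Writing $\omega_i$ for the basis (absolute) variances,
$t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$; under
the sparsity assumption (most $\rho_{ij} \approx 0$) the row sums of $t$
give the linear system $((D-2)I + J)\,\omega = t_\cdot$, solved directly.
The strongest remaining pair with $|\rho|$ above the exclusion threshold
(default 0.1) is then removed from the system and the solve repeated, up
to `sparcc_iterations` (default 10) rounds — without this, a few strong
pairs bias all basis variances.

Numerical choices:

* **Scale invariance.** Each sample is rescaled to a fixed *virtual depth*
  (default 1000) before the unit pseudocount is added, so the estimate is a
  function of relative abundances only and per-sample closure of the input
  cannot change it. An absolute pseudocount on raw densities would break
  this defining property whenever densities approach the pseudocount.
* **Pseudocount 1** on the virtual-count scale keeps zero cells from
  producing unbounded negative logs while distorting non-zero cells only
  mildly.
* **No Dirichlet resampling.** A single point estimate keeps the pipeline
  deterministic and testable; averaging over resampled fractions is a
  documented divergence from some implementations.
* $r$ is clipped to $[-1, 1]$; all-zero species are dropped with a warning;
  at least 4 species and 4 samples are required by the basis-variance
  system.

Significance comes from column permutations: each species' values are
shuffled independently across samples, destroying all pairwise
association while preserving marginals; with add-one smoothing
$p = (1 + \#\{|r^{perm}| \ge |r^{obs}|\})/(1 + B)$, floor $1/(1+B)$,
default $B = 100$.

`build_bipartite_network()` keeps exactly the cross-guild pairs with
$|r| \ge 0.3$ (inclusive — "filtered under the threshold" reads as
discarding values below it) and $p < 0.05$ (strict). Within-guild pairs
are never edges; species left without edges are excluded, so network size
counts networked taxa.

## Topology

Besides node/link counts and the proportion of negative links, the report
contains:

* **Links per species** = links / network size (exact ratio; rounding only
  for display).
* **Bipartite clustering.** Triangles cannot exist in a bipartite graph,
  so clustering is measured on same-guild pairs at distance two:
  $cc(u,v) = |N(u) \cap N(v)| / |N(u) \cup N(v)|$, averaged per node over
  partners sharing at least one neighbor, then over nodes. Published
  values computed with other tools may use a different convention and are
  not reproduction targets.
* **Quantitative linkage density** on $|r|$ weights: per node, the
  effective number of partners is $e^{H}$ with $H$ the Shannon entropy of
  its edge weights; linkage density is half the weight-share-weighted sum
  over both guilds, and **weighted connectance** is linkage density over
  network size. The connectance convention is pinned by the ratio identity
  (e.g. 2.375/45 = 0.053) rather than by reconstructing unavailable
  weights.

## Null models

`rewire()` performs Maslov-Sneppen double-edge swaps on the oriented
bipartite edge list (every edge stored guild-A → guild-B, so swapped
edges stay cross-guild by construction), rejecting swaps that would
duplicate an edge. Per null network, `10 × edges` attempts are made — the
standard mixing heuristic. Rewired edges carry the attributes of the first
parent edge, so the multiset of edge weights is conserved and weighted
metrics compare like for like; whether reference tools conserve weights is
unknown, so this convention is recorded here. Ensembles (default 1000
networks) yield per-metric null distributions; the empirical value is
compared by a one-sample Student's *t* test of the null vector against it.
Conserved metrics (link count, degree sums) produce a degenerate-null flag
instead of a *t* statistic.

## Stability

* **Robustness.** Per trial, `round(f × guild size)` nodes of the target
  guild are removed uniformly at random (banker's rounding), then any node
  left with zero edges is removed iteratively (secondary extinction);
  robustness is the surviving fraction of the *original* network size.
  The survival rule is binary (≥1 remaining link): the abundance-unweighted
  reading of interaction-strength-based survival; the weighted variant is
  out of scope.
* **Robustness curves** fit ordinary least squares to mean robustness vs
  removal fraction; two curves are compared by permuting trial labels
  within each fraction (999 permutations) with the mean difference of
  per-fraction means as statistic.
* **Global efficiency** $E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d(i,j)$ on
  unweighted hop distances, $1/d = 0$ for disconnected pairs. **Node
  vulnerability** is $(E - E_i)/E$ with node $i$ deleted ($n$ decremented);
  it can be negative for redundant nodes, and the network vulnerability is
  the maximum.
* **Subnetworks** anchored on a phytoplankton taxon group (e.g. diatoms)
  keep the group plus every zooplankton partner; subnetworks under 20
  nodes are flagged small.

## Modules and environment

Modules maximize modularity on $|r|$ weights via deterministic greedy
agglomeration (the algorithm name and seed are recorded; other algorithms
would give different partitions — a documented caveat, not hidden). On
tiny graphs the agglomeration can return an all-singleton cut with
negative modularity; the connected-component partition is then used as the
better-scoring coarser candidate. Node roles use the within-module degree
z-score $Z_i$ (0 when the module's within-degree sd is 0) and among-module
connectivity $P_i = 1 - \sum_s (k_{is}/k_i)^2$, with the four-way rule at
$Z_i = 2.5$, $P_i = 0.62$; non-peripherals are keystones.

A module's **eigenvalue series** is the first principal component of its
members' z-scored abundance profiles, unit variance, sign-oriented to
correlate positively with the mean member profile (removing PCA's sign
indeterminacy so correlation signs are reproducible). Factor correlations
are Pearson with the usual star convention.

**Preserved module pairs** across fractions share at least half the
*smaller* module's nodes: overlap $= |A \cap B| / \min(|A|,|B|) \ge 0.5$
(inclusive), matched greedily by descending overlap, one-to-one; the
min-denominator lets nested modules pair, with Jaccard available as an
option.

**Mantel tests** link node connectivity to environmental sensitivity:
species significance is the squared Pearson correlation of each networked
species' density with each factor of a group (temperature, salinity, pH
alone; N = the three nitrogen species; metal = Zn, Pb, As, Cu, Hg); the
statistic correlates the Euclidean distance matrices of connectivity and
of significance profiles, with 999 matrix permutations, per guild. The
exact construction used by the original analyses is not printed anywhere
recoverable, so published Mantel values are not reproduction targets.

## The synthetic world

The generator states one fixed world (defaults, not dials): 251 samples in
12 contiguous site blocks; 307 phytoplankton; 200 shared zooplankton
species plus 82 smaller-only and 40 bigger-only; smaller-fraction
densities 3× the bigger fraction (the field observation is a strong
decline of density with body size; 3 is a stated, plausible magnitude);
10% zero inflation; log-normal species baselines with spread 1.5 (few
dominant bloom taxa); site-level mean shifts (sd 0.5) enabling regional
networks; unit residual log noise.

Log-densities are latent-factor log-normals: a planted pair with strength
$s$ shares a latent normal factor with loading
$\sigma\sqrt{s/(1-s)}$, giving expected log-scale Pearson correlation $s$;
an environmental coupling with coefficient $c$ has expected log-scale
correlation $c$ with the (z-scored) factor. Per-species baselines and
site effects are drawn once and shared across fraction tables, so the
smaller/bigger density ratio is exact in expectation and the same species
in two fractions can be planted to covary. Optional closure rescales every
sample to a fixed total, creating exactly the compositional artifacts the
correlation method must remove.

What the generator does **not** emulate: real coastal species composition,
latitudinal diversity gradients, integer counting error, structural zeros
(zeros are independent Bernoulli thinning), temporal autocorrelation, or
true interaction mechanisms. A green end-to-end test therefore establishes
that the pipeline recovers *planted log-linear associations under
compositional distortion and sparsity* — not that inferred field networks
are ecologically true.

## Known limitations

* SparCC's sparsity assumption fails for densely correlated communities;
  the exclusion iterations mitigate but do not remove this.
* Module detection is algorithm-dependent; only the recorded algorithm and
  seed make partitions comparable.
* The bipartite clustering and linkage-density conventions match the
  definitions above, not any specific external tool.
* Permutation p-values have a floor of $1/(1+B)$; with the default
  $B = 100$, multiple-testing control is left to the caller.
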
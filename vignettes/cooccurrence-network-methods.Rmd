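---
title: "Methods: co-occurrence networks, node roles, and community statistics"
author: "MicrobeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, node roles, and community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicrobeNet)
```

# Scope

MicrobeNet turns a taxon-by-sample abundance table and a sample grouping
(for example, three agricultural management regimes with five soil
samples each) into:

1. per-sample alpha diversity (Chao1, Shannon, Pielou);
2. a signed co-occurrence network over the retained taxa, built from
   Spearman correlations screened by a correlation-magnitude cutoff and
   a Benjamini-Hochberg (BH) false-discovery-rate cutoff;
3. modules (communities) of that network, per-node Zi/Pi role
   coordinates, and a keystone classification;
4. topology summaries suitable for comparing networks across groups;
5. distance-based community statistics: Bray-Curtis dissimilarity,
   one-factor PERMANOVA, the Mantel test, non-metric multidimensional
   scaling (NMDS) with Kruskal stress-1, and variance-inflation-factor
   (VIF) screening of environmental covariates.

A synthetic community generator with planted, known structure makes the
whole chain testable without any sequencing data.

# The statistical model of the network stage

## Filtering

Taxa whose mean relative abundance across samples falls strictly below
`minMeanRel` (default `1e-4`, i.e. 0.01%) are dropped, as are taxa that
are zero everywhere. A taxon exactly at the threshold is kept. Survivor
abundances are left on their original scale: renormalising after
filtering would alter every remaining proportion for no inferential
gain in a rank-based analysis, and is available behind
`renormalize = TRUE` for users who want closed columns.

## Correlation and significance

`spearmanAssociation()` computes average-rank Spearman rho between all
taxon pairs and a two-sided p-value from the t approximation
`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
The approximation is accurate for the sample sizes where a network is
sensible (n >= 10) and is the only practical choice for thousands of
taxa; an exact permutation-null option (`exact = TRUE`, n <= 8) exists
so the approximation itself can be checked on small fixtures. Taxa with
constant profiles have no rank variance and are dropped with a warning.
Pairs with `|rho| = 1` receive `p = 0`.

BH adjustment is applied once to the strictly-upper-triangle p-values
and mirrored, so each unordered pair is counted exactly once in the
multiplicity `m`.

## Edge criteria

An edge is kept when `|rho| >= rCutoff` **and** the significance value
is `<= sigCutoff`. Both comparisons are inclusive, since the
conventional phrasing "cutoff was 0.5" does not specify strictness and
inclusive comparison keeps the partition unambiguous. The significance
value defaults to the BH-adjusted q (`useFdr = TRUE`) because FDR
correction precedes the cutoffs in the pipeline; raw-p screening is one
flag away. Three presets ship with the package — bacteria (0.5, 0.02),
fungi (0.50, 0.05), archaea (0.68, 0.05) — reflecting cutoff/confidence
pairs commonly applied per kingdom in soil-community studies. The
absolute value means negative (co-exclusion) edges survive; they carry
`sign = -1` and weight `|rho|`.

## Modules

`detectModules()` runs modularity clustering: deterministic greedy
agglomeration by default (the merge tree is cut explicitly at the
maximum-modularity step, which also repairs an igraph corner case where
the default cut stops one merge short on ties) or multi-level Louvain
behind a seed.

Sign handling was a genuinely open design point. Modularity treats
every edge as evidence of affinity, but a negative co-occurrence edge
is evidence of avoidance or of compositional coupling, not of shared
membership. On relative-abundance data, closure alone induces negative
correlation between any two groups of taxa that each occupy a
substantial share of the community, and letting those edges bind
modules together demonstrably merges genuinely distinct modules. The
default (`signAware = TRUE`) therefore clusters the positive-edge
subgraph; negative edges remain in the network for topology, role and
export purposes. `signAware = FALSE` restores clustering on the full
skeleton.

## Zi, Pi, and keystones

For node i in module s with within-module degree `k_is`:

* `Zi = (k_is - mean_s) / sd_s`, with mean and **population** standard
  deviation taken over the within-module degrees of s's members (the
  original role-cartography convention); `sd_s = 0` yields `Zi = 0`.
* `Pi = 1 - sum_t (k_it / k_i)^2` over modules t; an isolated node has
  `Pi = 0`.

Nodes are classified at `Zi = 2.5` and `Pi = 0.62` into peripheral,
connector, module hub and network hub. The four published inequalities
are strict on both sides and leave the boundary unassigned; MicrobeNet
counts boundary values as the hub/connector side so that the four
categories partition the plane. Keystones are all non-peripheral nodes.

## Topology

Node and edge counts (split by sign), average degree `2E/N`, diameter
and average path length by unweighted breadth-first search on the
largest connected component (thresholded co-occurrence graphs are
usually disconnected, and path lengths across components are
undefined), global clustering coefficient, and the modularity and
module count of the stored partition. Weights and signs are node/edge
attributes only; all topology is computed on the unweighted skeleton.

# Distance-based statistics

* **Bray-Curtis**: `d_ij = sum|x_i - x_j| / sum(x_i + x_j)` over taxa.
* **PERMANOVA**: Anderson's one-factor partition.
  `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` summed per group over
  within-group pairs divided by group size, pseudo-F from the usual
  mean-square ratio, `R^2 = SS_between / SS_total`. One factor only:
  the supported design is a single grouping such as management regime.
* **Mantel**: Spearman by default, matching the rank-based network
  philosophy; rows/columns of the second matrix are permuted jointly
  and the test is two-sided on `|r|`. Because a permutation of the
  samples permutes the pair vector, the implementation pre-ranks both
  upper triangles once and correlates permuted rank vectors, which is
  exact and considerably faster than re-ranking per permutation.
* **Permutation p-values** use `(1 + b) / (1 + m)`, so `p = 0` is
  impossible and the smallest attainable p with 999 permutations is
  0.001.
* **NMDS**: Kruskal-style stress-1 minimisation (vegan's `monoMDS`
  engine) from a principal-coordinates start plus `nRestarts` (default
  20) seeded random starts; the lowest-stress configuration is kept and
  a fit that only ever hits the iteration cap is flagged, not raised.
  Stress below ~0.1 is conventionally a good fit.
* **VIF screening**: iteratively drop the covariate with the largest
  `1/(1 - R^2)` until all fall below the threshold. 5 is the usual
  screen for soil covariates and 10 a documented laxer alternative;
  exactly collinear columns give infinite VIF and the later column (by
  input order) is dropped first, deterministically.

# The synthetic generator

`simulateCorrelatedCommunity()` draws, per sample, one standard-normal
latent value per module; taxon i in module m has log-abundance
`mu_i + groupEffect(i, g) + loading * z_m + eps`, `eps ~ N(0, noiseSd)`.
Keystone taxa additionally load, with the same loading, on a second
module's factor, which is what makes them among-module connectors by
construction. Log-abundances are exponentiated, multiplied by one fixed
scale chosen so a typical sample totals `librarySize` (default 100,000),
Poisson-sampled to counts, and then zeroed cell-wise with probability
`zeroInflation` (detection dropout). Defaults mirror a three-regime
soil study: 3 groups x 5 samples, 300 taxa, 3 modules, loading 0.8,
noise 0.3, 10% zero inflation, group-effect scale 0.5 — strong enough
group separation for a 15-sample PERMANOVA to detect without being
degenerate.

One numerical design choice deserves emphasis. Counts are produced by a
**fixed global scale**, not by closing each sample to exactly
`librarySize`. Per-sample closure couples every taxon to every other
through the shared denominator; with a few equally sized modules this
induces between-module correlations of roughly `-loading^2/3`, strong
enough to cross a 0.5 cutoff, and — more damagingly — it cancels most
of a two-module keystone's positive correlation to its own modules
while manufacturing a strong negative correlation to the remaining
module, turning the planted keystone into an anti-hub. A fixed scale
keeps the planted covariance interpretable on the count scale; the
pipeline itself still closes data to relative abundances where its
definitions require it. Poisson sampling (rather than negative
binomial) is sufficient because every downstream statistic is
rank-based; a dispersion knob is deliberately left out until something
consumes it.

What the generator does **not** emulate: taxon-specific dispersion,
phylogenetic correlation, true library-size variation between
ecological groups, sparse compositional effects at low depth, and any
functional (gene-level) structure. Tests passing on this generator
therefore validate the statistical machinery, not the biology of any
particular soil.

`simulateNullCommunity()` is the matching null: i.i.d. log-normal
counts, no groups, no correlation — used to calibrate the type-I error
of PERMANOVA and Mantel (nominal 5% level, checked against the
binomial envelope of 200 replicates at 999 permutations each in the
test suite).

# Determinism

Every stochastic step takes an explicit seed and restores the caller's
RNG state afterwards. The pipeline derives stage seeds from one master
seed and logs them; rerunning a config reproduces every output file
byte-for-byte. Greedy module detection is fully deterministic; Louvain
is deterministic given its seed.

# Problem sizes used by the test suite

Unit tests run on tables of 20-100 taxa and 9-30 samples, random graphs
up to 50 nodes (checked exactly against brute-force BFS and explicit
Zi/Pi loops), 1,000 random p-vectors against a step-up BH oracle, and
10-seed pipeline replicates at the strong-signal regime (3 modules x 20
taxa, 30 samples, loading 0.9, noise 0.3). Calibration uses 200 null
replicates at 999 permutations. These sizes keep the suite fast while
leaving every oracle comparison exact.

# Known limitations

* Spearman on relative abundances is blind to compositional artefacts;
  the package deliberately implements the plain-correlation pipeline,
  not SparCC/SPIEC-EASI-style compositionally aware estimators.
* One-factor PERMANOVA only; no strata, no interactions.
* Chao1 requires integer counts and is reported as `NA` on relative
  tables rather than silently mis-estimated.
* Role classification is threshold-based; nodes near (2.5, 0.62) change
  category under small perturbations, which is inherent to the scheme.
* Module detection on the positive subgraph treats strong co-exclusion
  structure as background; a signed-modularity objective would be the
  natural extension.
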
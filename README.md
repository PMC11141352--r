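# MicrobeNet

Microbial co-occurrence network analysis and community statistics from
taxon-by-sample abundance tables, in R.

Soil and other microbiome studies routinely ask two linked questions:
how do management or treatment regimes reshape a microbial community,
and which taxa hold that community together? MicrobeNet implements the
standard analysis chain for both, starting from an annotated abundance
table (an OTU/taxon × sample matrix of counts or relative abundances)
and a sample-to-group mapping:

1. **Filtering** — taxa with mean relative abundance < 0.01% (and
   all-zero taxa) are removed.
2. **Association** — all-pairs Spearman ρ with two-sided p-values from
   the t approximation `t = ρ√((n−2)/(1−ρ²))`, Benjamini–Hochberg FDR
   over the unique pairs; an edge is kept when `|ρ| ≥ r_cutoff` and
   `q ≤ sig_cutoff` (presets: bacteria 0.5/0.02, fungi 0.50/0.05,
   archaea 0.68/0.05). Edges are signed: ρ < 0 is co-exclusion.
3. **Modules and roles** — modularity clustering (greedy or Louvain),
   then the Zi–Pi role cartography: within-module connectivity
   `Zi = (k_is − μ_s)/σ_s` and among-module connectivity
   `Pi = 1 − Σ_t (k_it/k_i)²`, classified at Zi = 2.5, Pi = 0.62 into
   peripherals, connectors, module hubs and network hubs. Keystone taxa
   are the non-peripheral nodes.
4. **Topology** — node/edge counts by sign, average degree, diameter
   and average path length (largest component), clustering coefficient,
   modularity; per-sample induced subnetworks; GraphML/GEXF export for
   Gephi.
5. **Community statistics** — Bray–Curtis dissimilarity, one-factor
   PERMANOVA (pseudo-F, R², permutation p), Mantel tests, NMDS with
   Kruskal stress-1, and VIF screening of covariates.
6. **Synthetic data** — a latent-factor community generator with
   planted correlation modules, known keystones, group-level effects
   and zero inflation, so every stage above is testable against known
   truth.

The package is Bioconductor-style S4: `AbundanceTable`,
`AssociationResult`, `CoNetwork`, `PermutationResult`, `Ordination`
classes with validity checks, accessors and `show()` methods.

## Worked example

Simulate a strong-signal community (3 planted modules × 20 taxa, 30
samples, 3 keystone taxa wired across two modules each), then run the
chain:

```r
library(MicrobeNet)

sim  <- simulateCorrelatedCommunity(nTaxa = 60, samplesPerGroup = 10,
                                    nModules = 3, loading = 0.9,
                                    noiseSd = 0.3, zeroInflation = 0,
                                    nKeystones = 3, seed = 1)
filt  <- filterTaxa(sim$table)
assoc <- spearmanAssociation(filt$table)
edges <- thresholdEdges(assoc, edgeCriteriaPreset("bacteria"))
net   <- detectModules(buildNetwork(edges, taxonIds(filt$table)))
net
#> CoNetwork: 60 nodes, 530 edges (520 positive, 10 negative)
#>   3 modules (greedy)

topologySummary(net)
#>   n_nodes n_edges n_positive_edges n_negative_edges average_degree diameter
#> 1      60     530              520               10       17.66667        4
#>   average_path_length clustering_coefficient modularity n_modules
#> 1            2.080226              0.8185961  0.5784567         3

roles <- classifyRoles(ziPi(net))
head(roles[order(-roles$pi), ], 3)
#>         node module degree      zi    pi   category is_keystone
#> 1  taxon_001      3     13 -2.5325 0.497 peripheral       FALSE
#> 60 taxon_060      2     33 -1.1949 0.489 peripheral       FALSE
#> 30 taxon_030      2     27  0.0412 0.466 peripheral       FALSE
sim$truth$keystoneIds
#> [1] "taxon_001" "taxon_030" "taxon_060"
```

The detected modules recover the three planted blocks, and the three
highest-Pi nodes are exactly the three planted keystones (here their
Pi ≈ 0.47–0.50 stays below the 0.62 connector line — as in real soil
networks, the overwhelming majority of nodes classify as peripheral).
Group structure shows up in the distance-based stage:

```r
bc <- brayCurtis(sim$table)
permanova(bc, sim$metadata$group, nPerm = 999, seed = 2)
#> pseudo-F = 2.2596, R^2 = 0.143, p = 0.008 (999 permutations, seed 2)
nmdsOrdination(bc, k = 2, seed = 3)
#> Ordination: 30 samples in 2 dimensions, stress-1 = 0.1574
```

So management-style group effects explain ~14% of community variance
(significant at p = 0.008), and the 2-D NMDS embedding has moderate
stress.

`runPipeline(makeRunConfig(...))` orchestrates the whole chain from a
table + metadata TSV pair into a results directory (filtered table,
diversity, edges, GraphML, roles, topology, PERMANOVA/Mantel JSON, NMDS
coordinates, log, resolved config); `compareNetworks()` tabulates
topology and keystone counts across runs. A thin CLI wrapper lives at
`inst/scripts/conet-pipeline.R` (subcommands `simulate`, `run`,
`compare`).

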
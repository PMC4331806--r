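# ISHC

Synchronization-based hierarchical clustering of protein–protein
interaction (PPI) networks, with firefly-algorithm tuning of the
synchronization radius.

## The problem

Protein complexes appear in PPI networks as dense modules with sparse
boundaries. Classical partitioners struggle with the small-world,
scale-free character of interactomes; synchronization clustering instead
treats each protein as a coupled phase oscillator and lets cluster
structure emerge from the dynamics. ISHC is aimed at computational
biologists who have an interaction network (optionally confidence-weighted)
and want candidate complexes plus quality metrics against a reference
catalogue.

## The method

1. **Spectral preprocessing.** From the network, an edge-similarity matrix

   `A_ij = η (|N_i ∩ N_j| + 1) / min(|N_i|, |N_j|) + (1 − η) [Σ_{k∈I_ij} w(i,k) · Σ_{k∈I_ij} w(j,k)] / [Σ_{s∈N_i} w(i,s) · Σ_{t∈N_j} w(j,t)]`

   mixes the degree-based and the weighted edge clustering coefficient
   (`η = 0.5` by default). `A` is symmetrically degree-normalized,
   `L_ij = A_ij / √(D_ii D_jj)`, and each protein gets 3-D coordinates from
   the three top eigenvectors of `L`, row-normalized to the unit sphere.

2. **Synchronization clustering (SHC).** Objects within distance ε couple
   through `x(t+1) = x(t) + |N_ε(x)|⁻¹ Σ_{y∈N_ε(x)} sin(y − x)` per
   coordinate. A set whose ε-neighborhoods close on themselves (every
   member sees exactly the whole set) is guaranteed to synchronize, so it
   is frozen as a cluster immediately; the rest keep coupling until all
   objects are absorbed. Objects with no ε-neighbor become singleton
   clusters — the natural outliers.

3. **Radius optimization.** The quality of a partition is the weighted
   modularity `fval = Σ_H (2m_H / (2m_H + n_H))^ρ (w_in / (w_in + w_out))^(1−ρ)`
   (`ρ = 0.8` by default). A firefly swarm (6 fireflies × 30 iterations,
   `β₀ = 1`, `γ = 1`, `α = 0.9`) searches the 1-D ε space for the maximum;
   a hierarchical grid scan seeded by nearest-neighbor distances is the
   baseline alternative.

Evaluation against reference complexes uses maximum-matching
precision/recall and their harmonic mean (f-measure).

## Worked example

```r
library(ISHC)

sim <- plantedPartitionNetwork(rep(8, 3), pIn = 0.9, pOut = 0.02, seed = 1)
sim$network
#> PPINetwork with 24 nodes and 78 edges
#>   nodes: m1_1, m1_2, m1_3, m1_4, m1_5, ...
#>   weights in [1, 1]

X <- embedNetwork(sim$network, eta = 0.5)
fit <- optimizeEpsilon(X, sim$network, faParams(seed = 1), rho = 0.8)
fit$clustering
#> Clustering of 24 objects into 3 clusters (epsilon = 0.377767, 0 sync steps)
#>   cluster sizes: 8 8 8

m <- precisionRecallF(fit$clustering, sim$complexes)
unlist(m[c("precision", "recall", "fMeasure")])
#> precision    recall  fMeasure
#>         1         1         1
fit$value
#> [1] 2.961524
```

The three planted 8-protein modules are recovered exactly: at the optimized
radius (ε ≈ 0.378) each module is already an ε-neighborhood closure, so no
synchronization sweeps are needed, every predicted cluster matches its
module perfectly (precision = recall = 1), and the modularity objective is
close to its ceiling of 3 (one per cluster; boundary edges keep it just
below).

The same pipeline is scriptable from a shell:

```sh
ishc=$(Rscript -e 'cat(system.file("scripts", "ishc.R", package = "ISHC"))')
Rscript $ishc simulate --modules 3x8 --p-in 0.9 --p-out 0.02 --seed 1 -o data
Rscript $ishc cluster  --edges data/edges.tsv --seed 1 -o out
Rscript $ishc evaluate --pred out/clusters.tsv --ref data/complexes.tsv --edges data/edges.tsv
```

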
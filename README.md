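# otccc

Optimal-transport distances and clustering for directed cell–cell
communication graphs.

## What problem this solves

Single-cell RNA-seq cohorts let us infer, per patient sample, a
**cell–cell communication (CCC) network**: a directed weighted graph whose
nodes are cell types and whose edge `u -> v` carries the summed
ligand–receptor interaction score from sender `u` to receiver `v`.
Clustering patients by these networks — e.g. separating disease sub-groups
with distinct communication programs — requires a distance between directed
weighted graphs that respects both edge *direction* and network *topology*.
`otccc` provides such a distance and the clustering machinery around it, for
anyone analysing per-sample edge tables produced by tools such as
CellPhoneDB/LIANA-style LR scoring followed by per-sample aggregation.

## Method in brief

1. **Shared topology graph (STG).** All samples share one node set, so the
   union of their edges defines a single directed *line graph*: each vertex
   is a directed cell-pair edge, and vertex `(u,v)` links to `(v,w)`
   (head-to-tail). Line-graph edges are weighted by the fraction of samples
   containing both original edges.
2. **Hitting-time ground metric.** The STG, row-normalized and mixed with a
   PageRank-style teleportation term `alpha` (default 0.05), is an
   irreducible Markov chain with stationary distribution `pi`. With
   `Q[i,j]` the probability of hitting `j` before returning to `i`, the
   normalized hitting-time matrix `T[i,j] = sqrt(pi_i) sqrt(pi_j) Q[i,j]`
   (diagonal 1) gives the ground cost `C = -log T` between directed
   interactions. An alternative normalization
   `T[i,j] = sqrt(pi_i/pi_j) Q[i,j]`, which is exactly symmetric, is
   available as `variant = "similarity"`.
3. **Wasserstein distances.** Each sample's edge weights, zero-padded over
   the union edge set and normalized to total mass 1, is a distribution on
   STG vertices. Sample distances are balanced optimal transport under `C`
   (exact network-simplex LP by default; entropic Sinkhorn and a
   KL-relaxed unbalanced variant are provided, as is a correlation-distance
   baseline cost).
4. **Clustering.** Either k-medoids (PAM) on the distance matrix, or a
   k-barycenters EM algorithm whose centroids are fixed-support Sinkhorn
   barycenters: assign each sample to its nearest barycenter (exact LP
   distance), recompute barycenters, repeat; multi-restart with
   farthest-point seeding, keeping the restart with the lowest mean
   Wasserstein loss. Barycenters are themselves edge distributions, i.e.
   interpretable "average" CCC networks, and transport maps between them
   show which interactions shift between clusters.

## Worked example

```r
library(otccc)

# a synthetic two-group cohort: 10 cell types, ~75 directed interactions,
# 2 x 10 samples, 5-fold hub effect, 10% lognormal noise
sim <- generate_cohort(cohort_spec(seed = 7))
S   <- build_edge_signal_matrix(sim$cohort)   # 20 x 73 signal matrix

stg <- build_stg(sim$cohort)
P   <- regularized_transition(stg, alpha = 0.05)
C   <- htd_cost(P)                            # ground metric over 73 edges
range(C[upper.tri(C)])
#> [1] 4.329261 5.629786

D   <- pairwise_distances(S, C)               # 190 exact LP solves
km  <- k_medoids(D, k = 2)
kb  <- k_barycenters(S, C, k = 2, n_restarts = 5, seed = 1, D = D)

adjusted_rand_index(km$labels, sim$true_labels)
#> [1] 1
adjusted_rand_index(kb$labels, sim$true_labels)
#> [1] 1
silhouette_score(D, kb$labels)$mean
#> [1] 0.8657538
```

Both algorithms recover the planted groups exactly (ARI 1), and the mean
silhouette of 0.87 confirms two well-separated clusters in the Wasserstein
geometry. `kb$representatives` holds the two barycenter distributions;
`write_signal_edges()` renders them as edge lists for plotting.

A pipeline front-end (reading an edge table, writing distance matrix,
labels, barycenters, transport maps and a run manifest) is available as
`run_pipeline(make_run_config(...))` and as a thin command-line script
installed at `exec/otccc` (subcommands `simulate`, `run`, `evaluate`).

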
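---
title: "Methods: optimal transport between directed cell-cell communication graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal transport between directed cell-cell communication graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Each sample $k$ in a cohort is a directed weighted graph
$G_k = (V, E_k, w_k)$: nodes are cell types (identical across samples,
because all samples come from the same annotated dataset), a directed edge
is a predicted communication event from a ligand-expressing to a
receptor-expressing cell type, and its weight is the sum of the
ligand-receptor interaction scores for that ordered cell-type pair.
Self-loops are legitimate (autocrine signalling). Weights are non-negative;
a weight of 0 is indistinguishable from an absent edge in this model, so
zero-weight rows are dropped at parse time.

Collecting the union of edges over all samples gives the signal matrix
$P \in \mathbb{R}^{p \times E}$: row $k$ is sample $k$'s edge-weight
vector, zero-padded on edges it lacks. The working hypothesis is that all
samples share one latent topology and differ in the *signal* they place on
it; comparing samples then means comparing distributions over a common
support, which is exactly what optimal transport (OT) does.

### Mass conservation

We use *balanced* OT: every sample's signal is normalized to total mass 1,
i.e. we assume the overall amount of communication is comparable across
samples and only its *allocation* differs. This is an assumption, not a
theorem; the package therefore also ships an unbalanced variant
(`unbalanced_wasserstein()`) in which the marginal constraints are replaced
by KL penalties of strength `rho`, for users who expect genuine gains or
losses of communication mass. In our synthetic experiments the balanced
form is used throughout.

## The shared topology graph and its Markov chain

The ground cost of the OT problem must encode how "far apart" two directed
interactions are. We build the directed line graph over the union edge set
(the *shared topology graph*, STG): vertex $(u, v)$ connects to $(v, w)$ —
signal can flow from an interaction into interactions emitted by its
receiver. The line-graph edge weight is the fraction of samples containing
both endpoints, so transport between commonly co-occurring interactions is
cheaper than between rarely co-observed ones. A self-loop edge $(A, A)$ is
head-to-tail compatible with itself; its diagonal entry is simply its own
occurrence frequency. This follows from applying the compatibility rule
literally and keeps the chain's treatment of autocrine edges consistent.

Line graphs of sparse cohorts can be disconnected, and hitting times are
only defined on an irreducible chain. We therefore row-normalize the
adjacency and mix with the uniform distribution,
$P = (1-\alpha) D^{-1} W + \tfrac{\alpha}{E} J$ — the standard PageRank
construction. Two conventions needed fixing where the construction is
otherwise open:

* **Dangling vertices** (no outgoing compatible edge) get a uniform row
  *before* mixing — the usual PageRank treatment.
* **Mixing level**: the teleportation is applied at the transition level
  (after row normalization), not to the adjacency. This is the PageRank
  convention and keeps $\alpha$ interpretable as a probability.

`alpha` defaults to 0.05: large enough to guarantee strict positivity
(hence a unique stationary distribution and well-defined hitting
probabilities), small enough to perturb the chain geometry minimally. It is
exposed everywhere.

## Hitting-time distance

For the chain $P$ with stationary distribution $\pi$ ($\pi P = \pi$,
computed by a dense linear solve up to 2000 states, power iteration above,
validated against the fixed-point residual at $10^{-8}$), let
$Q_{ij}$ be the probability that a walk from $i$ hits $j$ before returning
to $i$. We compute $Q$ one *target* column at a time: with $j$ absorbing,
the expected number of visits to $i$ before absorption is the diagonal of
the fundamental matrix $N = (I - P_{-j,-j})^{-1}$, and since each excursion
from $i$ independently reaches $j$ first with probability $Q_{ij}$, the
visit count is geometric and $Q_{ij} = 1/N_{ii}$. One $O(E^3)$ solve per
column serves all sources, $O(E^4)$ total — trivial at the problem sizes
here ($E \le$ a few hundred directed interactions).

The normalized hitting-time matrix and cost are
$$T_{ij} = \pi_i^{1/2}\, \pi_j^{1/2}\, Q_{ij} \;(i \ne j),\qquad
T_{ii} = 1, \qquad C = -\log T .$$

The exponent of the second $\pi$ factor is a genuinely open choice: the
product form above (`variant = "as_printed"`, the default) bounds every
off-diagonal cost below by $\log 2$ (because
$\sqrt{\pi_i \pi_j} \le 1/2$ and $Q \le 1$) but is not symmetric; the
similarity-transform form $T_{ij} = \sqrt{\pi_i/\pi_j}\, Q_{ij}$
(`variant = "similarity"`) is exactly symmetric, because the stationary
probability flux identity $\pi_i Q_{ij} = \pi_j Q_{ji}$ holds for every
irreducible chain. Both are implemented; tests assert the $\log 2$ bound
for the first and machine-precision symmetry for the second. Because
downstream sample distances inherit symmetry from the ground cost, the
default pipeline symmetrizes the cost, $C \leftarrow (C + C^\top)/2$, with
the diagonal forced to exact 0. The triangle inequality of the resulting
sample distance matrix is checked on sampled triples in the test suite
rather than assumed.

## Transport solvers

* **Exact LP** (default for pairwise distances): a transportation simplex
  (MODI) implemented in C++ — greedy minimum-cost initial basis completed
  to a spanning tree by union-find, Dantzig pivoting with a switch to
  Bland's rule after a run of degenerate pivots, reduced-cost tolerance
  $10^{-11}$. Zero-mass atoms are stripped before the solve and the plan is
  re-embedded. The solver is validated against an independent generic
  simplex (`boot::simplex`) to $10^{-9}$ on randomized instances.
* **Sinkhorn** (used for barycenters, available for distances): log-domain
  stabilized scaling, so small regularization values do not underflow. The
  default $\varepsilon$ is 1% of the maximum ground cost; the reported
  value is $\langle \Gamma_\varepsilon, C\rangle$, which decreases to the
  LP value as $\varepsilon \to 0$ (asserted on fixed instances). Entropic
  quantities are never exactly zero at $p = q$; tests assert smallness, not
  equality.
* **Unbalanced**: KL-relaxed Sinkhorn scalings with exponent
  $\rho/(\rho+\varepsilon)$; reported value
  $\langle \Gamma, C\rangle + \rho\,\mathrm{KL}(\Gamma 1 \| p) +
  \rho\,\mathrm{KL}(\Gamma^\top 1 \| q)$. At large $\rho$ with normalized
  inputs it reproduces the balanced Sinkhorn value (within 1% in tests).
* **Correlation baseline** (`corr_cost()`): $1 -$ Pearson correlation
  between signal-matrix columns, a topology-blind ground cost for
  comparison. Zero-variance columns take correlation 0 (distance 1 to
  everything) by stated convention.

## Clustering

**k-medoids** uses deterministic greedy BUILD initialization followed by
assign/update alternation, ties always to the lowest index — the result is
reproducible without any randomness.

**k-barycenters** is EM in Wasserstein space. Barycenters are fixed-support
entropic barycenters computed by iterative Bregman projections (a shared
kernel, per-member scalings, weighted geometric-mean coupling), converged
when successive iterates move less than $10^{-6}$ in $L^1$ (up to $10^4$
inner iterations; heterogeneous supports after dropout converge the
slowest). Assignment uses the *exact* LP distance — deterministic and free
of entropic bias where it matters (the labels).

Three design points where the algorithm statement leaves room:

* **Monotonicity safeguard.** The entropic barycenter optimizes a
  regularized surrogate of the assignment loss, so an M-step could in
  principle worsen the exact mean loss. Each new barycenter is therefore
  accepted only if it does not increase its cluster's mean exact loss.
  With that guard, the monitored objective — the mean over samples of the
  distance to the assigned barycenter, i.e. the $\tfrac1p\sum_i
  d_W(G_i,\mu_{y_i})$ objective — is non-increasing across EM iterations by
  construction, and the test suite asserts it per restart. (The guard can
  be bypassed only by the empty-cluster repair, which re-seeds a dead
  cluster with the worst-served sample; this did not occur under the study
  conditions.)
* **Restart selection.** The EM is restarted (default 100 times; 5 in the
  test suite and acceptance script, which is ample at desk scale) and the
  restart with the lowest mean Wasserstein loss is kept; per-cluster mean
  losses are reported alongside.
* **Seeding.** Farthest-point seeding by default (first pick uniform at
  random from the seed, each next pick maximizes the distance to the
  nearest chosen sample); a probabilistic squared-distance sampling mode is
  provided as an alternative since both readings of "maximize
  cluster-to-cluster distance" are defensible. The pairwise sample distance
  matrix is computed once and shared across restarts, so only the first
  pick differs between restarts.

Silhouette analysis (`silhouette_score()`, via the `cluster` package) and
`sweep_k()` (ARI / Rand index over a k range, per seed) support choosing k
and benchmarking against known labels. ARI and the Rand index are computed
from the contingency-table formulas and cross-checked in the tests against
`mclust` and `e1071`.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` emulate what LR analysis of a real
cohort produces, with known ground truth:

| parameter | default | meaning |
|---|---|---|
| `n_cell_types` | 10 | graph nodes |
| `density` | 0.75 | P(directed edge present), self-loops included |
| `n_groups` x `samples_per_group` | 2 x 10 | cohort layout |
| `effect_size` | 5 | fold-change on hub-incident edges |
| `sigma` | 0.1 | lognormal jitter (sdlog) per sample and edge |
| `dropout` | 0 | per-sample edge removal probability |
| `base_sdlog` | 0.5 | spread of baseline edge means |

The defaults mirror a pancreatic-cancer-sized cohort: 10 cell types at
density 0.75 give roughly 75 directed interactions per sample. Group
effects are applied to the edges incident to a group-specific *hub* cell
type (disjoint across groups), mimicking a disease-linked cell type whose
communication is amplified; lognormal multiplicative noise is used because
LR scores are positive and right-skewed. `downsample_signal()` emulates
sequencing fewer cells by binomial thinning of edge weights at a count
resolution `scale` (default 100 counts per weight unit), so the expected
weight scales by `keep_fraction` and the relative noise grows as signal is
removed.

What the generator does **not** emulate: batch effects, sample-specific
cell-type composition shifts, correlated (pathway-level) edge noise, and
the upstream LR-inference error process. Passing the recovery tests
therefore demonstrates that the distance and the clustering algorithms work
as designed under realistic graph dimensions and noise — not that any
particular real cohort will separate as cleanly.

## Problem sizes and empirical behaviour

The test suite and the acceptance script run at the generator's study
conditions (20 samples, ~75 edges, 5 EM restarts; hitting-probability
Monte-Carlo checks with $10^5$ walks on chains of up to 8 states; LP-oracle
checks at up to 4 atoms; triangle-inequality checks on 1000 sampled
triples). Under those conditions, both k-medoids and k-barycenters recover
the planted two-group structure at ARI 1 across seeds; with the group
effect removed the ARI collapses to ~0; recovery degrades monotonically as
jitter grows; and binomial thinning to 37.5% of the signal leaves recovery
essentially unchanged. All of these are computed by the tests and
`scripts/acceptance.R`, not quoted from anywhere.

## Known limitations

* The `"as_printed"` cost is not a metric in the strict sense (no symmetry
  before symmetrization; the triangle inequality is checked empirically,
  not proven), which is why both the symmetrized default and the
  `"similarity"` variant exist.
* $O(E^4)$ hitting-probability computation and dense $E \times E$ solves
  cap practical cohorts at a few thousand distinct directed interactions.
* The unbalanced formulation fixes KL penalties; other divergences are out
  of scope.
* Cell-type labels are opaque strings: no harmonization across samples is
  attempted beyond a warning when a label appears in fewer than half the
  samples.
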
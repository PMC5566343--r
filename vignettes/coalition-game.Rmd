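---
title: "Detecting protein complexes as coalitions of a sequential game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes as coalitions of a sequential game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(nashpdc)
```

## The model

A protein–protein interaction (PPI) network is an undirected simple graph
$G = (V, E)$: nodes are proteins, edges are observed physical interactions.
Protein complexes appear in such networks as small, densely interconnected,
low-diameter subgraphs, while some proteins belong to no complex at all.
`nashpdc` formalises this as a *partial dense vertex cover*: a collection of
pairwise-disjoint vertex subsets $C_1, \dots, C_k \subseteq V$ such that each
$C_i$, on its induced subgraph, satisfies

* **degree density** $\alpha(C_i) = \min_{v \in C_i} d_v / (|C_i| - 1) \ge \lambda$,
* **edge density** $\delta(C_i) = |E(C_i)| / \binom{|C_i|}{2} \ge \gamma$,
* **diameter** $R(C_i) = \max_{u,v \in C_i} |SP(u, v)| \le p$
  (a disconnected subset counts as infinite diameter),
* **local maximality**: no outside unassigned vertex can be added without
  breaking one of the above,

with $0 < \lambda \le \gamma \le 1$ and integer $p \ge 1$, and such that the
residual vertices contain no further subset meeting these constraints.
Vertices covered by no $C_i$ are reported as singleton clusters, so every
protein is either in a complex or alone.

Rather than optimising a global objective, the cover is found by playing a
sequential non-cooperative game in which every node is a selfish player.
A round has three moves:

1. **Proposal.** The highest-priority active player invites its closed
   $p$-th order neighborhood (restricted to active players) to form a
   coalition. Priority — the *rule of order* — is the geometric mean
   $\sqrt{d_v \, t(v)}$ of degree and local transitivity, computed once on
   the full graph, descending; ties break by degree then identifier.
2. **Best response.** Invitees accept only when membership is individually
   rational, which this package operationalises as feasibility-restoring
   refinement (next section).
3. **Resolution.** If a feasible, locally maximal coalition survives, it is
   stable: its members quit the game. Otherwise the proposer is exhausted
   (it never proposes again, though it may still join later proposals).

The game ends when every active player has been exhausted. A fixed point of
these dynamics — no player can gain by unilaterally leaving or joining — is
a Nash equilibrium of the underlying strategic-form game, and the emitted
partition is a partial dense vertex cover.

## The refinement procedure

The accept/reject narrative does not pin down a computation, so the package
commits to one deterministic best-response procedure in
`refine_coalition()`:

* **Prune.** While any constraint is violated and more than `min_size`
  members remain, the non-proposer member with the smallest
  within-coalition degree leaves (ties: lexicographically larger identifier
  first). Removing the weakest-connected member is the greedy step that
  most directly raises both $\alpha$ and $\delta$, the two quantities the
  players' preference relation orders; the proposer is never pruned because
  the proposal is defined around its neighborhood.
* **Fail.** If the constraints still fail at `min_size`, the proposal
  collapses and every invitee stays in the game.
* **Grow.** Otherwise the coalition is extended to local maximality: among
  active non-members adjacent to the coalition, the vertex with the most
  links into it joins whenever its addition preserves all constraints
  (ties: lexicographically smaller identifier first), repeatedly. Because
  an accepted coalition must have diameter at most $p$, growth can never
  escape the proposer's $p$-ball.

Every step is deterministic, so identical input and configuration always
reproduce the identical cover, including coalition order. One proposal per
player keeps termination immediate and the per-proposal work bounded by the
$p$-ball size, giving the $O(N(\log N + d_{max}^p))$ overall behaviour
expected for this family of local-search detectors.

`verify_cover_set()` re-checks all defining properties of a returned cover
independently of the engine's bookkeeping; with
`exhaustive_residual_check = TRUE` it also enumerates *every* subset of the
residual (capped at `residual_bound` vertices) to certify that nothing
detectable was left behind. The test suite uses this, plus brute-force
oracles coded separately from the package internals, on hundreds of small
random graphs.

## Parameters

| parameter  | default | meaning                                        |
|------------|---------|------------------------------------------------|
| `lambda`   | 0.6     | degree-density floor $\lambda$ (dimensionless) |
| `gamma`    | 0.65    | edge-density floor $\gamma$, $\ge \lambda$     |
| `p`        | 2       | diameter bound and proposal radius             |
| `min_size` | 3       | smallest set reported as a complex             |

The `lambda`/`gamma`/`p` defaults are the classical illustration values for
this game on dense complexes. `min_size = 3` excludes bare edges from being
called complexes while still admitting small true complexes. Sparse,
low-density complexes can be sought simply by passing tiny floors
(e.g. `pdc_config(lambda = 0.001, gamma = 0.001)`); nothing else changes.

The floors are *absolute*: a set of $k$ proteins needs at least
$\gamma \binom{k}{2}$ internal interactions. With the defaults, a coalition
is roughly "two-thirds of a clique", which targets compact, assembly-like
complexes and deliberately refuses loose communities.

## Synthetic benchmarks and what they show

`generate_gn()` draws the classic planted 4-partition benchmark: 128 nodes
in four modules of 32, each intra-module pair linked with probability
$p_{in} = z(1-\mu)/31$ and each inter-module pair with
$p_{out} = z\mu/96$, so every node has expected degree $z$ (default 16)
and an expected fraction $\mu$ of its edges leaving its module.
`generate_er()` draws the matched $G(n, p)$ null model and
`rewire_edges()` perturbs a graph by re-pointing each edge endpoint to a
uniformly random vertex with probability $\rho$, discarding collisions.
All three are bit-reproducible for a fixed seed. Recovery is scored by
`nmi()` — twice the mutual information of the class labels over the sum of
the class entropies — against the planted partition, with residual vertices
entering as singleton classes; contingency-based scores (`sn_ppv_acc()`,
`matching_score()`) instead exclude residual singletons from the predicted
complexes by default, since singleton clusters are not complex predictions.

One structural fact deserves emphasis, because it determines what the
default configuration can and cannot do on these benchmarks. A planted
module of 32 vertices has expected internal edge density
$p_{in} = 16(1-\mu)/31 \le 0.52$ — below the default $\gamma = 0.65$ for
every $\mu$. Whole planted modules therefore *cannot* be coalitions at the
default floors; the game instead extracts the dense sub-complexes inside
them (typically 14–24 coalitions of size 3–7 per network, as
`run_gn_sweep()` reports), and the NMI against the planted partition
plateaus well below 1 even at low mixing. Exact module recovery on such
comparatively sparse community benchmarks requires floors chosen below the
within-module density — a regime the sweep functions accept but do not
default to. For the same reason the matched Erdős–Rényi null model is not
coalition-free at the defaults: a $G(128, 16/127)$ graph contains hundreds
of triangles, and a triangle is a perfectly dense feasible set at
`min_size = 3`; `run_er_null()` consequently reports small triangle-scale
coalitions, not module-scale structure. Raising `min_size` (or the floors)
empties the null model. Both behaviours are properties of the model's
absolute density constraints, not of the implementation; the package
reports them as measured.

The shift experiment (`run_shift_test()`, `shift_module()`) probes a
detected or planted module from a different angle: replacing 20% of its
members with adjacent outsiders should *decrease* its connectivity density
(within-module degree mass over total edge count) if the module is a
genuinely dense local subgraph. On planted benchmark modules this direction
holds for every module, averaged over hundreds of randomisation replicates.

## Numerical choices and degenerate inputs

* Density comparisons are exact ratio-against-literal comparisons in double
  precision; no tolerance is added, so a set with $\delta$ mathematically
  equal to $\gamma$ passes.
* The diameter test uses boolean powers of $A + I$: the set has diameter
  $\le p$ iff $(A+I)^p$ is everywhere positive; disconnection therefore
  fails the test without a separate check.
* Singletons have $\alpha = \delta = 0$ and diameter 0, so they never meet
  positive floors; vertices of degree $< 2$ have local transitivity 0,
  keeping the rule of order total.
* All orderings (rule of order, prune/grow tie-breaks, output files) fall
  back to radix (C-locale) identifier order, making every code path
  deterministic across platforms and locales.
* An edgeless or feasibility-free network yields an empty coalition list
  with every vertex residual; the all-vertex "grand coalition" can never be
  proposed because proposals are $p$-balls.

## Problem sizes used in validation

The shipped tests and the acceptance script use desk-scale replicates
chosen as reasonable Monte-Carlo sizes for their purpose: 20 benchmark
instances per sweep point (standard errors on mean NMI around 0.005), 200
random graphs of up to 12 vertices for exhaustive-enumeration equivalence,
and 300 shift replicates per module. The generators and runners accept
larger counts unchanged; the canonical experiment in this literature uses
100 instances per point (`instances = 100`, the `run_gn_sweep()` default).

## Limitations

* Coalitions are disjoint by construction; overlapping complexes are out of
  scope (a protein that plausibly belongs to two complexes is assigned to
  the first stable coalition that claims it).
* Edge weights and interaction confidence scores are ignored.
* The engine returns one equilibrium partition; equilibria need not be
  unique, and a different (but equally fixed) tie-break convention could
  return a different one.
* A failed proposer never re-proposes. In principle a feasible set could
  survive in the residual because every member's single greedy proposal
  collapsed; the exhaustive verifier is provided exactly to detect this,
  and finds no such case across the shipped random-graph batteries.
* Absolute density floors make recovery of sparse planted communities a
  parameter choice, not a default (see above); users benchmarking against
  community-detection generators should set the floors relative to the
  expected within-module density.
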
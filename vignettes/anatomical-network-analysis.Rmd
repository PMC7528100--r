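---
title: "Anatomical network analysis of skull topology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical network analysis of skull topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullnet)
```

## The network model and its assumptions

A skull is represented as an undirected, simple graph: one node per
individual bone, one link per pair-wise physical articulation (suture or
synchondrosis). The representation is binary — either two bones
articulate or they do not — so contact area, suture interdigitation and
3-D geometry are deliberately outside the model. Bones fused without a
visible suture are a single node; `fuse_bones()` implements exactly this
as node contraction, which is also how the synthetic generator simulates
ontogenetic and evolutionary fusion.

Three structural invariants are enforced at construction time and after
every edit: the graph is simple (no self-articulations, no duplicate
links), connected (a skull is one structure, and the mean path length L
is undefined on a disconnected graph), and has at least two bones and
one articulation. Bone names are case-sensitive and whitespace-trimmed;
the canonical ordering used for serialization is lexicographic. Paired
bones are kept as distinct left/right nodes (`L.`/`R.` prefixes in the
generator); unpaired midline bones are single nodes.

## The eight topological variables

For a network with `N` bones and `K` articulations:

* **D** `= 2K / (N(N-1))`, the fraction of realised articulations,
  in (0, 1].
* **C**, the mean local clustering coefficient in [0, 1]: per bone, the
  fraction of realised triangles among its neighbours. A bone with
  fewer than two neighbours has no candidate triangle; we define its
  local coefficient as 0, consistent with reading low C as "neighbouring
  bones do not connect". The alternative convention — excluding such
  bones from the mean — is available via
  `net_clustering(isolates = "exclude")`.
* **L**, the mean shortest-path length over unordered bone pairs,
  in [1, N − 1]; self-pairs are excluded.
* **H**, the heterogeneity of connections: the coefficient of variation
  of the degree sequence, using the population standard deviation, so a
  regular network has H = 0 exactly. The degree-variance variant is
  offered (`formula = "variance"`) because the literature is not
  uniform on this point; the CV is the default and the one the test
  oracles pin down.
* **A**, Newman degree assortativity in [−1, 1]: the Pearson correlation
  of end-point degrees over the (doubled) edge list. On degree-regular
  networks the correlation is 0/0; `net_assortativity()` returns `NA` as
  an explicit undefined flag rather than raising an error. Because a PCA
  cannot carry missing values, `profiles_table()` imputes flagged values
  as 0 — the natural "no preference" point of the scale — with a
  warning naming the specimens. This matters in practice: very small,
  highly fused skulls are the ones that go regular.
* **P** `= 1 − Σ (n_i/N)²` over the sizes of the disjoint module
  partition: 0 for a fully integrated (single-module) skull, `1 − 1/S`
  for S equal modules. P is the only variable that needs a module
  partition as input.

All metric implementations are cross-checked in the test suite against
independent brute-force oracles (triangle enumeration, all-pairs BFS,
direct degree formulas, edge-wise correlation) on every connected graph
with up to seven nodes, to 1e−12.

## Module detection: node-based informed strategy

Whole-graph community detection on small anatomical networks is
unstable; the node-based strategy instead asks, for every bone, "which
module does this bone sit in?" and then reconciles the answers:

1. **Local search.** For each bone a single-community spinglass search
   (simulated-annealing Potts model; 25 spin states, resolution
   γ = 1, standard geometric cooling) anchored at that bone returns the
   community containing it. Per-bone seeds are derived from one master
   seed (`seed + bone index`), so the whole detection is reproducible; a
   failed annealing run is retried with an incremented seed, a bounded
   number of times. A whole-graph spinglass variant is available
   (`method = "global"`), anchored search being the default.
2. **Deduplication.** Identical candidate sets are collapsed.
3. **Merging of redundant candidates.** For every pair of remaining
   candidates, the probability of their observed overlap under random
   draws from the N bones is the upper-tail hypergeometric probability;
   a significantly large overlap (Bonferroni-adjusted over the current
   candidate pairs, α = 0.05) marks the two candidates as redundant
   descriptions of one module and they are replaced by their union.
   This repeats to a fixed point, re-adjusting over the shrinking pair
   set each round. The surviving modules may overlap — anatomical
   modules genuinely share boundary bones — and a single surviving
   module is a valid outcome for small, highly fused skulls.
4. **Disjoint partition.** P needs exactly-one assignment, so each bone
   goes to the module holding the largest fraction of its
   articulations; ties break to the larger module, then to the first
   module label. The rule is deterministic, so repeated runs agree.

For N ≤ 5 simulated annealing is unreliable and the detector switches
to exhaustive maximum-modularity partitioning (all set partitions, at
most 52 of them; ties toward fewer modules). This is the regime of the
most heavily fused adult bird skulls.

The redundancy criterion (deduplicate, then merge on significant
hypergeometric overlap) is this package's documented interpretation of
"merging non-redundant modules"; it is the main place where a
reasonable alternative reading exists, which is why both the raw merge
log (sizes, overlap, raw and adjusted p) and the detection parameters
are kept on the returned object.

## Morphospace and group tests

The eight variables are column-centered and scaled to unit sample
variance (n − 1 denominator) and decomposed by SVD; the variance
fraction of PC i is σᵢ²/Σσ². The number of PCs is
min(specimens − 1, 8). Signs of principal axes are arbitrary, so a
convention is fixed — the largest-magnitude loading of each PC is made
positive — making scores reproducible across BLAS backends and row
orderings. A zero-variance column is a hard error naming the column,
not a silent drop.

PERMANOVA uses the distance-matrix form of the one-way pseudo-F: with
squared Euclidean distances `d²`, `SS_total = Σ_{i<j} d²_ij / n`,
`SS_within = Σ_g Σ_{i<j∈g} d²_ij / n_g`, and
`F = (SS_between/(a−1)) / (SS_within/(n−a))`. On Euclidean coordinates
this equals the classical trace pseudo-F via group centroids, which the
tests exploit as an independent oracle (and cross-check against
`vegan::adonis2`). Significance comes from unrestricted label
permutations, `p = (#{F* ≥ F} + 1)/(m + 1)`, with m = 10,000 by
default; for tiny cohorts `permutations = "exact"` enumerates all
distinct label arrangements and returns the exact tail fraction. The
test runs on all retained PCs by default — Euclidean distance on the
full score matrix equals distance on the scaled variables themselves,
so no information is lost — and `n_pcs` restricts it to leading PCs
when a truncated morphospace is wanted.

`run_grouping_suite()` applies the tests over grouping schemes (any
metadata column) and subsample rules, recomputing the PCA per subsample
because variance fractions are cohort-dependent. Built-in rules mirror
comparative practice: `all`, `no-birds` (drop all crown birds) and
`no-adult-birds`. Schemes whose levels collapse after subsampling
(fewer than two groups, or any group smaller than two) are skipped with
a message rather than tested meaninglessly.

## What the synthetic generator emulates — and what it does not

`make_template_skull()` builds one half of a skull as a spanning tree
over index-ordered bones plus extra short-range edges (index distance
≤ 3), mirrors it, and joins the halves through a chain of midline bones
anchored at matching positions on both sides. The short-range
construction mimics the spatial locality of sutural contact — skull
bones articulate with neighbours, not across the skull — which an
Erdős–Rényi graph would not. Defaults give densities around 0.15–0.25,
inside the 0.1–0.5 band of real skull networks.

`simulate_fusion_trajectory()` implements Williston's law as repeated
node contraction: candidate pairs are drawn among current
articulations, same-module pairs up-weighted by a bias factor (bones
within a module are the ones that tend to fuse in ontogeny), and a
fused left-side pair co-fuses its mirrored right-side counterpart with
probability 0.9 — paired bones typically fuse bilaterally. Every
contraction, co-fusions included, is one event, so the final bone count
is exactly the initial count minus the number of events.

`make_cohort()` draws per-specimen fusion counts from group-specific
ranges. The default cohort has 25 specimens on 44-bone templates
(19 per side + 6 midline, matching adult non-avian theropod bone counts
of roughly 32–44): a 13-specimen "basal" group with 0–4 fusions and a
12-specimen "derived" group with 16–24 fusions, emulating the contrast
between little-fused skulls and the heavily fused skulls of adult crown
birds. Identical ranges in both groups give a null cohort for type-I
calibration.

The generator reproduces the *statistical* structure the analysis
relies on — bilateral symmetry, sparsity, planted modularity,
group-level fusion differences — not real anatomy: there are no real
bone identities, no ontogenetic ordering of suture closure, no
taxon-specific articulation patterns, and fusion events are
conditionally independent given the bias. Passing tests therefore
demonstrate that the pipeline recovers known structure of this kind;
they do not validate anatomical conclusions about any real taxon.

## Numerical choices and problem sizes

* Spinglass hyperparameters: 25 spins, γ = 1, default igraph cooling;
  chosen as the standard Potts-annealing settings. Detection seeds all
  derive from one master seed.
* Hypergeometric merge threshold α = 0.05 with Bonferroni adjustment
  over candidate pairs, recomputed each merge round.
* Exact PERMANOVA enumeration is refused above 1e5 arrangements.
* Tie-breaks are everywhere deterministic and documented (partition
  assignment; exhaustive partitioning toward fewer modules).
* Floating-point comparisons in permutation counting use a 1e−10 slack
  so ties at F itself count as exceedances on both routes.

The test suite exercises: all 995 connected graphs on 2–7 nodes
(metric oracles); 3 × 8 planted partitions at p_in = 0.8 /
p_out = 0.05 over 10 seeds (module recovery, NMI ≥ 0.9); exact
enumeration at n = 6 (PERMANOVA); 500 null datasets of 16 specimens
(type-I calibration, rejection rate 0.05 ± 0.02); and 20 random fusion
trajectories (bookkeeping). These sizes keep the full suite under a
minute on one CPU while leaving each check statistically meaningful.

## Known limitations

* Spinglass annealing is stochastic; module counts on ambiguous
  networks can vary by ±1 across seeds even though each run is
  reproducible from its seed. The merge log and parameter record are
  kept precisely so such runs can be audited.
* The hypergeometric merge treats modules as unordered bone sets; it
  ignores the graph structure inside the overlap.
* Assortativity imputation (undefined → 0) injects a small bias toward
  the centre of the A axis for regular networks; the raw profiles keep
  the flag so users can handle it differently.
* PERMANOVA assumes exchangeability of specimens under the null;
  phylogenetic non-independence is not corrected for (no
  phylogenetically informed PCA or permutation scheme is provided).
* Binary articulations only: no weighted or directed variants.
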
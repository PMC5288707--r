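---
title: "Temporal dynamics-sensitive centrality: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal dynamics-sensitive centrality: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcnet)
```

## The problem

In a temporal contact network the substrate of an epidemic is a sequence
of `L` snapshot adjacencies `A(1) … A(L)` on a fixed node set, one per
time bin of width `δ`. Infections can only travel along time-respecting
routes: a contact that happens *before* the infection reaches its
endpoint is useless. Structural centralities — whether computed on the
aggregated (time-collapsed) network or on the time-ordered graph — rank
nodes by topology alone and carry no notion of the infection (`β`) and
recovery (`μ`) rates that determine how far an outbreak actually travels.
`tdcnet` ranks nodes by a quantity with dynamical content: the expected
epidemic mass a node seeds.

## The linearized SIR recursion

The discrete-time SIR model infects a susceptible node with probability
`β` per infectious contact per step and recovers infectious nodes with
probability `μ` per step (`μ = 0` gives SI). Writing `x(t)` for the
vector of cumulative ever-infected probabilities and approximating the
infection probability of a node with `m` infectious neighbours by `mβ`
(linear coupling), the dynamics close into a linear recursion: the
infectious mass vector evolves as `y(r) = H(r) y(r−1)` with

`H(t) = β A(t) + (1 − μ) I`,

and the newly infected mass at step `r` is `P(r) = β A(r) y(r−1)`,
starting from the seed indicator `x(0)`. The temporal
dynamics-sensitive centrality of node `i` at horizon `t` is
`S_i(t) = Σ_j x_j(t)` with `i` the sole seed.

Three modelling consequences are worth keeping in mind:

* **Overestimation.** Linear coupling overestimates infection
  probabilities, and `x(t)` is a cumulative quantity that may exceed 1.
  It is read as an influence *measure*, not a probability; the package's
  tests verify on small networks that the recursion upper-bounds the
  Monte Carlo ever-infected frequencies (within Monte Carlo error), and
  that in the small-`β`, short-horizon regime theory and simulation agree
  closely.
* **Periodic boundary.** Snapshots beyond `L` cycle: `A(L+1) = A(1)`.
  This lets horizons exceed the recorded window and gives the threshold
  construction a well-defined one-period propagator. `snapshotAt()` also
  offers a `truncate` mode that refuses indices past `L`.
* **Static reduction.** With all snapshots equal, TDC collapses to the
  dynamics-sensitive centrality of static networks; the test suite checks
  this against an independently coded dense implementation.

## Computing the scores

Two routes are implemented and cross-checked against each other (to
1e-10 relative) on random temporal networks:

* `route = "perseed"`: run the recursion once per node (`N` sweeps of
  sparse matrix–vector products).
* `route = "onepass"` (default): since every `A(t)` is symmetric, the
  whole score vector equals `S = Σ_r H(1)⋯H(r−1) (β A(r) V)` with `V`
  the all-ones vector. This is evaluated backwards, Horner-style:
  `acc ← β A(r) V + H(r) acc` for `r = t, …, 1`. Memory is one sparse
  snapshot plus a handful of dense vectors; no left-product matrix is
  ever materialized.

Scores are reported **unnormalized**: the evaluation metric (Kendall tau)
is invariant to monotone rescaling. `normalizeScores()` implements
min–max rescaling to `[0, 1]` (a constant vector maps to zeros, by
convention), and `shiftedScores()` adds 1 — a plotting convenience that
puts normalized analytic scores on the same axis as simulated mean
outbreak sizes, which are at least 1. Min–max was chosen as the
normalization because it is the form that a "+1" translation onto the
outbreak-size axis presupposes; nothing downstream depends on the choice.

## Epidemic threshold

Over one period the linearized dynamics are governed by the infection
propagator `M = Π_{t=1..L} [β A(t) + (1 − μ) I]` (chronological order).
The epidemic threshold `β_c` solves `ρ(M(β)) = 1`.

Numerical choices:

* `ρ(M)` is computed by **power iteration applying the L factors
  sequentially** to a vector — the dense product is never formed. The
  start vector is all-ones (deterministic, strictly positive), the
  iterate is renormalized every sweep, and iteration stops when the
  per-sweep growth factor changes by less than 1e-10 (relative), with a
  cap of 1e5 sweeps. Because the factors are entrywise nonnegative, the
  dominant eigenvalue is real and equals the spectral radius. A
  stabilized two-sweep estimate covers imprimitive corner cases (for
  example `μ = 1` on bipartite snapshots) where single-sweep growth
  ratios alternate.
* `β_c` is found by **bisection** on `[0, betaMax]` (default `[0, 1]`,
  since `β` is a probability), valid because `ρ` is continuous and
  nondecreasing in `β`; the default bracket tolerance is 1e-6.
* Degenerate regimes are handled explicitly: no edges at all is an
  error; `ρ(M(0)) = (1 − μ)^L ≥ 1` can only happen at `μ = 0`, which
  returns `β_c = 0` with a warning; `ρ(M(betaMax)) < 1` raises a
  "no threshold in range" error. Disconnected aggregated networks emit a
  warning (the radius is then the maximum over components).

The tests pin the closed form `β_c = μ/λ_max` for repeated static
networks, compare `ρ` against dense eigendecompositions on random
instances, and check the periodicity law `ρ(M_k) = ρ(M)^k` and cyclic
(but not arbitrary) reordering invariance.

## The SIR simulator

The simulator uses the **exact nonlinear coupling** `1 − (1 − β)^k` — the
analytic recursion approximates, the simulation is the ground truth.
Within a step `s` (on snapshot `A(s)`, resolved periodically when the
horizon exceeds `L`):

1. susceptible nodes with `k` infectious neighbours at the start of the
   step become infected with probability `1 − (1 − β)^k`;
2. nodes infectious at the *start* of the step recover with probability
   `μ` (a node cannot recover in the step it was infected);
3. newly infected nodes become infectious at the next step.

This order was chosen because it is the discrete scheme whose
linearization reproduces `x(1) = β A(1) x(0)` and
`P(2) = β A(2) H(1) x(0)` exactly on chains; the alternative
(recover-before-infect) would not. Reproducibility uses per-(seed node,
replicate) substreams derived from a base seed with a Lehmer-style mix
kept below 2³¹, so per-seed results do not depend on evaluation order.

## Benchmark centralities

Static degree, closeness and betweenness are computed on the aggregated
binary network (shortest paths and pair dependencies via igraph). The
printed closeness form `1/Σ_j d_ij` is undefined on disconnected
aggregates; there the harmonic form `Σ_j 1/d_ij` (unreachable → 0) is
used, with a message. Betweenness counts unordered pairs once and
excludes endpoints.

The temporal variants operate on the time-ordered graph with **one
contact-edge hop per snapshot and free waiting**:

* temporal distance: earliest-arrival BFS; distance is the number of
  window steps used;
* temporal degree: snapshot degree averaged over the window;
* temporal closeness: `Σ_j 1/Δ_ij`, unreachable contributing 0;
* temporal betweenness: earliest-arrival route counting by
  forward/backward dynamic programming on the time-layered graph. Routes
  are counted as *walks* (contact sequences; a route through `i` counts
  once per arrival at `i`): exact simple-path filtering is exponential,
  and on the sparse short-window instances where the measure is
  validated the two notions coincide (the tests compare against
  exhaustive enumeration). Source–target pairs are directional, since a
  time-respecting route from `j` to `k` generally has no counterpart
  from `k` to `j`.

These variants are deliberately plain formulations of the standard
temporal-centrality ideas; they serve as ranking baselines, and the tau
comparisons that consume them are insensitive to positive rescaling.
With equal snapshots and a window at least as long as the diameter,
temporal and static closeness agree in ranking up to the ties that
`1/Σd` cannot resolve — the tests assert that no node pair is ordered
strictly oppositely.

## Time-order null model

The null model destroys time order while conserving topology exactly:
each (pair, event) can be relocated to a uniformly drawn snapshot of the
*same* pair, accepted only if that slot is empty for the pair (an
occupied slot, including the current one, is a rejected move). Per-pair
contact counts, the aggregated network, `N` and `L` are conserved by
construction; the tests assert this exactly on a thousand fuzzed
instances and validate mixing (the slot distribution of a lone event is
uniform by a chi-square test over 10⁴ seeded shuffles).

Two operationalizations were open and are settled as follows: "completely
randomized" is a fixed number of full sweeps (default 10; there is no
natural stopping rule, and mixing is validated empirically), and the move
is a *relocation* rather than an event swap — a swap between two events
of the same unweighted pair would be a no-op, so the empty-slot validity
condition identifies relocation as the intended kernel. Moves of
distinct pairs commute, so the sweep may process pairs in any
interleaving; the implementation visits all events in a fresh global
random order per sweep (in compiled code, driven by R's RNG).

## Evaluation pipelines

`kendallTau()` computes tau-b (tie-corrected; simulation means at small
run counts produce ties, so tie correction is required) and errors on
constant inputs, naming the offending side. `methodComparison()` ranks
each method against the simulated influence across a `β` grid,
recomputing TDC per `(β, μ)` and structural methods once.
`timeOrderImpact()` compares the original TDC ranking `S` with the
ensemble mean `S'` over shuffled networks at horizon `t = L`, reporting
tau and a dispersion of two standard deviations of the per-shuffle taus.

## Synthetic generators

`generateTemporalBA()` emulates a temporal scale-free test network: `L`
mutually *independent* BA snapshots (default `m = 1`, so each snapshot is
a 499-edge tree at `N = 500`) on a shared labeled node set, with the node
order re-randomized per snapshot so hubs move across time; a
`persistentHubs` flag keeps the attachment order fixed instead. Both the
independence across snapshots and `m = 1` are modelling choices for a
minimal heavy-tailed temporal substrate; the generator does not emulate
features of real contact data such as circadian rhythm, burstiness,
link persistence, or community structure — so passing tests on it
demonstrate correctness of the algorithms and the qualitative
threshold-dependence of time-order effects, not quantitative predictions
for any real system. `generateTemporalER()` provides structureless
fixtures, and `toyFixture()` the deterministic three- and four-node
examples used throughout the tests (the forward/reversed chains isolate
time-order sensitivity: reversing two snapshots changes which nodes are
reachable).

## Problem sizes and tolerances used in the checks

The automated checks run at desk scale, chosen to exercise every code
path with comfortable margins: route equivalence and static reduction on
~100/50 random networks up to `N = 50`, `L = 20` at 1e-10 relative
tolerance; threshold closed forms to 1e-6 in `β`; the chain simulator at
10⁵ replicates against exact enumeration (three standard errors); and
the time-order impact experiment on temporal BA networks with `N = 200`,
`L = 50`, 50-shuffle ensembles, with `β` set per network at the computed
`β_c` and at `4β_c` (bisection tolerance 1e-4 there — `β_c` only serves
as an operating point). The experiment uses `μ = 0.1` and horizon
`t = L`. Full-size runs (10⁴ SIR replicates, 10³ shuffles, real contact
datasets) use the same functions with larger arguments, e.g. through the
CLI.

## Known limitations

* Undirected, unweighted, instantaneous contacts only; no interval
  contacts, directed edges, or streaming input.
* The linear coupling makes TDC a relative ranking tool, not an outbreak
  size predictor, especially for large `β` or long horizons.
* Temporal betweenness counts walks, not simple paths (see above), and
  none of the temporal variants implement waiting-time-weighted path
  costs.
* The threshold assumes the periodic extension of the observed window;
  for very small `L` the finite-window correction is not modelled.
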
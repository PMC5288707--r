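# tdcnet

Ranking the spreading influence of nodes in **temporal contact networks**.

Many contact systems — e-mail exchanges, face-to-face proximity, message
boards — are not static graphs but sequences of snapshots: the network
looks different in every time bin, and an epidemic can only travel along
*time-respecting* paths. Purely topological centralities (degree,
closeness, betweenness, static or temporal) ignore the spreading dynamics
and can misrank potential super-spreaders. `tdcnet` implements a
**temporal dynamics-sensitive centrality (TDC)** that scores every node by
the expected epidemic mass it seeds under a linearized discrete-time SIR
process running on the actual snapshot sequence, together with the
supporting machinery needed to study it: the epidemic threshold of a
temporal network, a Monte Carlo SIR simulator as ground truth, six
benchmark centralities, a time-order randomization null model, and
Kendall-tau evaluation pipelines. It is aimed at researchers in network
epidemiology and temporal network analysis.

## The model

A temporal network is a fixed node set with `L` symmetric binary snapshot
adjacencies `A(1) … A(L)`, each covering a time bin of width `δ`. The SIR
dynamics have per-contact infection probability `β` and per-step recovery
probability `μ`. Under linear coupling (a susceptible node with `m`
infectious neighbours is infected with probability `mβ`), the expected
infectious mass propagates through the step matrix

```
H(t) = β A(t) + (1 − μ) I
```

and for a single seed `x(0)` the newly-infected probability vector at step
`r` is `P(r) = β A(r) H(r−1) ⋯ H(1) x(0)`. The TDC score of node `i` is
the total cumulative infected probability over all nodes at horizon `t`
when `i` is the sole seed:

```
S_i(t) = Σ_j x_j(t),   x(t) = Σ_{r≤t} P(r).
```

Because every `A(t)` is symmetric, the whole score vector is obtained in a
single backward (Horner) pass of sparse matrix–vector products,
`S = Σ_r H(1) ⋯ H(r−1) (β A(r) V)` with `V` the all-ones vector — no
per-seed loop and no dense matrix product. With all snapshots equal, TDC
reduces to the classic dynamics-sensitive centrality of static networks.

Snapshots beyond `L` are resolved periodically, `A(L+1) = A(1)`. Over one
period this defines the **infection propagator**
`M = Π_t [β A(t) + (1 − μ) I]`; the epidemic threshold `β_c` is the
infection probability at which the spectral radius `ρ(M)` crosses 1,
computed here by power iteration on the factor sequence and bisection in
`β`.

## Worked example

```r
library(tdcnet)

## a 3-node chain: A-B in snapshot 1, B-C in snapshot 2
net <- toyFixture("chain_forward")
p   <- spreadingParams(beta = 0.1, mu = 0.1, horizon = 2)
scores(tdcScores(net, p))
#>    A    B    C
#> 0.11 0.19 0.09
```

`B` scores highest (`β(2 − μ) = 0.19`): it can spread in both snapshots.
`A` beats `C` (`0.11 = β + β²` vs `0.09 = β(1 − μ)`) because A's contact
happens *before* the B–C contact, so a two-hop time-respecting route
A→B→C exists — time order matters even though A and C are topologically
interchangeable in the aggregated network. The Monte Carlo simulator
agrees: the mean outbreak from seed A over 10⁵ runs is `1.1103 ≈ 1 + S_A`.

```r
## epidemic threshold: single edge repeated, mu = 0.1 -> beta_c = mu / lambda_max
k2 <- temporalNetwork(rep(list(rbind(c(0, 1), c(1, 0))), 3))
epidemicThreshold(k2, mu = 0.1)
#> ThresholdResult: beta_c = 0.0999999 (mu = 0.1, rho = 0.99999971, 20 bisection steps)

## how much does time order matter? shuffle event times within each pair
net <- generateTemporalBA(200, 50, m = 1, rngSeed = 11)
bc  <- epidemicThreshold(net, mu = 0.1, tol = 1e-4)@betaC
timeOrderImpact(net, betaValues = c(bc, 4 * bc), muValues = 0.1,
                nShuffles = 50, rngSeed = 5)
#>    mu       beta       tau dispersion nShuffles
#> 1 0.1 0.05038452 0.4097487 0.06656397        50
#> 2 0.1 0.20153809 0.1696482 0.08736353        50
```

The Kendall tau between the original ranking `S` and the ranking on
time-shuffled networks `S'` drops as `β` moves away from `β_c`: the
further the dynamics are from threshold, the more the time order of
contacts shapes who the influential spreaders are.

A thin command-line front end over the same functions is installed at
`inst/cli/tdcnet.R` (subcommands `generate`, `threshold`, `simulate`,
`centrality`, `shuffle`, `evaluate`, `nullexp`) for running the pipelines
on timestamped edge-list files (`u v time` per line).

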
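---
title: "Comparing directed biological networks between two groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing directed biological networks between two groups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wnes)
```

## The problem

A signalling cascade, gene-regulatory module or systems-epidemiology
pathway can differ between two physiological conditions — cases and
controls, treated and untreated — in two distinct ways: the *nodes* can
change level (a gene is expressed more strongly) and the *edges* can change
strength or even direction (a regulation weakens, or flips).  Classical
single-marker tests see only the first kind of change; topology-only
network-comparison scores see only the second.  `wnes` tests the global
null hypothesis *"the network is the same in both groups"* with statistics
that aggregate both kinds of change and let the network's wiring decide how
much each node matters.

The networks handled here are directed acyclic graphs (DAGs) with known
structure — typically curated pathways.  Feedback loops are out of scope:
the topological weighting below counts descendants, which is undefined in
the presence of cycles, and the simulator's recursive data model requires a
topological order.

## The statistics

Let the two groups be D and C with sample sizes $n_1$, $n_2$, and let the
merged structure contain the union of the group node sets ($K$ nodes) and
the union of the directed edge sets ($M$ edges).  A node or edge absent
from one group contributes zero-filled summaries (mean, variance,
coefficient, coefficient variance all $0$) for that group, so presence
differences count as differences.

For node $k$, with group sample means $\bar x_{D,k}$, $\bar x_{C,k}$ and
unbiased variances $s^2_{D,k}$, $s^2_{C,k}$:

$$U_k = \frac{(\bar x_{D,k} - \bar x_{C,k})^2}
            {s^2_{D,k}/n_1 + s^2_{C,k}/n_2},$$

the square of the Welch two-sample $t$ statistic.  Edge strength is the
structural regression coefficient: each child is regressed (with
intercept) on **all** of its parents in its own group's network, and
$\hat\beta_m$ for edge $m$ is the coefficient of that edge's parent, with
its usual OLS sampling variance $\widehat{\mathrm{Var}}(\hat\beta_m)$ on
$n - p - 1$ degrees of freedom.  Then

$$V_m = \frac{(\hat\beta_{D,m} - \hat\beta_{C,m})^2}
            {\widehat{\mathrm{Var}}(\hat\beta_{D,m}) +
             \widehat{\mathrm{Var}}(\hat\beta_{C,m})}.$$

The five statistics are

* $NS = \sum_k U_k$ (nodes only),
* $ES = \sum_m V_m$ (edges only),
* $NES = NS + ES$,
* $WNES = \sum_k w_k U_k + ES$, with topological node weights $w_k$,
* $RT$, an aligned-rank statistic described below.

If the denominator of a term is zero while its numerator is zero the term
is defined as $0$ (an element constant and equal in both groups carries no
evidence); a zero denominator with a nonzero numerator is surfaced as an
error, because a constant node that differs in level between groups is a
data pathology the analyst should see, not absorb.

### Topological weights

The weight of a node grows with its downstream reach.  With $c_k$ the
number of *distinct descendants* of node $k$ (every node reachable along
directed paths, found by exhaustive downstream traversal — not merely
direct children, although `descendant_counts(mode = "children")` exposes
that alternative reading) and $r_k = c_k / \sum_j c_j$ its relative weight,
the default family is

$$w_k = 1 + \frac{K\, r_k}{a}, \qquad a > 0,\ \text{default } a = 1,$$

so a childless node has weight exactly $1$ and a node's excess weight is
its descendant count divided by the network-average descendant count,
scaled by $1/a$.  A power family $w_k = (1 + K r_k)^{1/b}$ is also
provided; in both, *smaller* tuning values give topology *more* say, and
`family = "unit"` recovers the unweighted $NES$.  The additive form was
chosen because it is the simplest form with the two properties that define
the weighting: baseline one for childless nodes, and an added term
proportional to the node's share of downstream reach.

### The aligned-rank statistic RT

$RT$ ignores the network.  Each column is optionally standardized over the
pooled sample (recommended when nodes carry different units), then aligned
by subtracting its pooled median.  Within every subject the $K$ aligned
values are ranked (midranks on ties), and with $\bar W_D$, $\bar W_C$ the
group mean rank vectors,

$$RT = \frac{n_1 n_2}{n_1 + n_2}\,
       \lVert \bar W_D - \bar W_C \rVert^2 .$$

The leading scalar is immaterial under permutation (any positive multiple
gives the same p-value); it is kept for scale familiarity.  A
rank-covariance (Mahalanobis) weighting of the distance is a possible
variant of this statistic; the unweighted Euclidean form is implemented
because the inverse rank-covariance is ill-conditioned at small $n$ and
the permutation calibration does not require any variance normalisation.

### Reversed edges

When the two group networks orient the same node pair oppositely, two
conventions are offered.  By default the orientations are distinct union
edges ($i \to j$ and $j \to i$ are different biology), so a single reversal
turns $M = 15$ into $M = 16$ and each orientation is zero-filled in the
group lacking it.  With `collapse_reversed = TRUE` the pair occupies one
shared edge slot and each group's coefficient is estimated in its *own*
orientation and compared directly — the convention under which a pure
direction flip with equal coefficients is invisible to the edge terms.

## Permutation inference

The null distribution of these statistics depends on the network wiring,
so no portable asymptotic reference exists; significance comes from group
label permutation: subjects are reassigned to two groups of the original
sizes, the *entire* pipeline (means, variances, per-child OLS in each
group's own structure, weighting, ranking) is recomputed per reassignment,
and the p-value is the proportion of permuted statistics at least as large
as the observed one.  Two conventions are provided: `empirical` reports
exactly that proportion (possibly $0$); `conservative` reports
$(\#\{T^\ast \ge T\} + 1)/(B + 1)$, which is never zero and is
finite-sample valid.  The observed arrangement is *not* silently added to
the permutation set.  All five statistics are evaluated on **one shared
permutation stream** per run, so their p-values are comparable across
statistics.  Permutation indices are drawn in R (so a seed pins the entire
stream); the per-split recomputation runs in compiled code, which keeps
500 permutations of a 12-node, 200-subject problem below a tenth of a
second.

## The simulator

`linear_sem()` places a linear Gaussian structural equation model on a
DAG: root nodes are $N(\delta, \sigma^2)$, every other node is
$\delta_j + \sum_{i \in \mathrm{pa}(j)} \beta_{ij} X_i + \varepsilon_j$
with independent Gaussian errors.  This is exactly the model under which
the per-child OLS recovers the generative coefficients, and
`implied_moments()` gives the closed-form mean and covariance by
accumulation in topological order — the oracle against which the simulator
is tested.

### Benchmark fixtures

Three built-in synthetic networks drive the simulation studies (all are
stand-ins wired for this package, not transcriptions of curated pathways):

* `upr12` — 12 nodes, 15 edges; one root chaperone (`GRP78`) activating
  three signalling branches (`ATF6`, `PERK`, `IRE1`) that reconverge on
  shared targets, with descendant counts ranging from 11 down to 0, so the
  weight distribution is strongly heterogeneous;
* `upr12_rev` — the same network with the designated edge
  `IRE1 -> TRAF2` reversed;
* `wnt35` — 35 nodes, 79 edges over Wnt-pathway gene symbols, built by a
  fixed deterministic scheme (a forward backbone tree plus seeded extra
  forward edges), used to check behaviour on a larger, denser structure.

The benchmark SEM places $\beta = 0.5$ on every edge, error variance
$\sigma^2 = 1$ everywhere, intercept $2$ on the root and $0$ elsewhere.
The nonzero root intercept propagates into heterogeneous node means, which
is the realistic regime for rank-based analysis (perfectly exchangeable
zero-mean columns are a degenerate special case for `RT`).

### Scenarios and rectification

`build_scenario()` produces the group-C model for seven canned designs:
no change (`null`), node-only mean shifts (`I`), edge-only coefficient
changes (`II`), edge change plus a shift on a heavily weighted node
(`III`), edge change plus a shift on a childless node (`IV`), and a single
edge reversal analysed with the orientations distinct (`dir-I`) or
collapsed (`dir-II`).

Perturbing a coefficient would, left alone, drag every downstream node's
mean and variance with it, confounding an "edge-only" scenario with
incidental node changes.  `rectify_sem()` therefore walks the perturbed
model in topological order and resets each node's intercept and error
variance so its implied marginal mean and variance equal the baseline —
except that explicitly shifted nodes keep their intended mean offset.
Because the model is Gaussian, matching means and variances makes the
marginal distributions of untargeted nodes *identical*, not merely
similar.  If a coefficient increase pumps more variance through a node's
parents than its baseline marginal variance, no non-negative error
variance can compensate and the scenario is reported as infeasible, naming
the node.

Direction scenarios rectify **means only**: a reversal redistributes
variance between the two endpoint nodes, and that redistribution *is* the
change under study — matching the variances too would erase nearly the
entire footprint of the reversal.  Mean preservation is still required, or
the reversal would masquerade as a set of node-mean changes.

### Effect sizes

The canned power scenarios use one fixed set of effect sizes, chosen once
so that the statistics land in the informative mid-range of power
(roughly 0.5–0.9) at 100 subjects per group: node shift $0.5$ on `GRP78`
(scenarios I and III; the maximal-weight node, $w = 1 + 12 \cdot 11/41
\approx 4.2$) or on the childless `GADD34` (scenario IV, $w = 1$), and
coefficient change $-0.4$ on `GRP78 -> ATF6`.  All are overridable through
`fixture_scenarios()` or the `simulate` subcommand.

## Calibration harness and problem sizes

`rejection_rate()` estimates type-I error (under `null`) or power (any
other scenario) by full Monte-Carlo replication: simulate both groups,
run the joint permutation test, count $p \le \alpha$.  The default desk
scale is 500 replicates of 500 permutations (Monte-Carlo standard error
$\approx 0.01$ at the nominal $0.05$); the package's own validation suite
runs the 12-node calibration at 500/500 and the 35-node at 300/300, and
the power suite at 500 replicates of 250 permutations, sizes at which the
whole study completes in a few minutes on one processor.  Larger grids
(e.g. 1000 replicates of 1000 permutations across five sample sizes) are
a configuration change, not a code change.

## What the simulation does and does not show

The simulator emulates complete, continuous, jointly Gaussian data with
exact linear structural equations and known structure.  Passing the
calibration and power checks therefore demonstrates correctness of the
statistics and their permutation inference *under the generative model* —
it does not certify behaviour under model misspecification: non-Gaussian
or heavy-tailed noise, nonlinear regulation, measurement error, missing
data (rejected, never imputed) or a wrong network structure.  The test is
also conditional on the supplied DAG; it does not learn structure.

One analytical limitation deserves emphasis.  After pooled-median
alignment, jointly Gaussian columns with group-equal means are centred in
both groups, and for a centred Gaussian vector every pairwise ordering
probability is exactly $\tfrac12$ regardless of covariance; the expected
within-subject mean rank vector is then $(K+1)/2$ in both groups.  The
Euclidean mean-rank `RT` consequently has no first-order power against
*covariance-only* alternatives (pure edge or pure direction changes with
means preserved) under Gaussian data — its empirical rejection rate stays
at the nominal level in those scenarios, as the package's own power suite
reports.  `RT`'s strength is mean-pattern changes, where it is competitive
with `NS` while being robust to monotone marginal transformations; rank
statistics sensitive to correlation changes would need a different
construction (e.g. rank-covariance comparison), which is outside this
package's scope.

## Numerical conventions

* Variances are unbiased ($n - 1$); OLS residual variance uses
  $n - p - 1$.
* OLS solves the normal equations via a Cholesky factorisation; an exactly
  collinear parent design is an error naming the child node.
* Ties in `RT` take midranks.
* Label matching is exact and case-sensitive everywhere; merging refuses
  node sets whose labels collide up to letter case, since that is almost
  always an upstream harmonisation bug.
* `simulate_sem()` accepts $\sigma^2 = 0$ (degenerate, useful for exact
  pipeline tests); scenario rectification refuses it, since a
  deterministic node makes the permutation statistics degenerate.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; harness replicates derive per-replicate seeds
  from the run seed, so any single replicate can be reproduced in
  isolation.

## A worked run

```{r example}
nets <- fixture_networks()
sem <- fixture_sem(nets$upr12)
scen <- build_scenario(sem, "III",
                       node_shifts = c(GRP78 = 0.5),
                       edge_deltas = c("GRP78->ATF6" = -0.4))
xD <- simulate_sem(scen$sem_D, 100, seed = 1)
xC <- simulate_sem(scen$sem_C, 100, seed = 2)
fit <- network_permutation_test(xD, xC, scen$net_D, scen$net_C,
                                B = 500, seed = 3)
fit
```

The decomposition in `fit$result` localises the signal: `fit$result$U`
holds the per-node squared standardized differences (largest at the
shifted `GRP78`), `fit$result$V` the per-edge terms (largest at the
altered `GRP78 -> ATF6`), and `fit$result$weights` the topological
weights that distinguish `WNES` from `NES`.
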
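---
title: "Growth coupling by solution-space subdivision: model, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth coupling by solution-space subdivision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncubeprod)
```

## The model and its assumptions

A constraint-based metabolic model is a stoichiometric matrix $S \in
\mathbb{R}^{m\times n}$ over $m$ internal metabolites and $n$ reactions,
with flux bounds $LB \le x \le UB$ (mmol/gDW/h). Flux balance analysis
assumes steady state, $Sx = 0$, and reduces any cellular question to a
linear program over the resulting polytope. Two designated reactions
carry the design question: the biomass (growth) reaction, whose flux is
the growth rate GR, and the target-metabolite export, whose flux is the
production rate PR. A knockout set $K$ is modelled by $x_j = 0$ for
$j \in K$.

Growth coupling asks for a $K$ such that, when the cell maximizes growth,
it *cannot avoid* producing the target. The package judges this with a
two-stage LP (`validate_deletion()`): maximize GR under the deletions,
then — holding GR at that maximum — *minimize* PR. The reported PR is
therefore a worst-case guarantee, not an optimistic co-optimum. A
strategy is accepted when both `min_growth` and `min_target` hold.

The search scans sub-boxes of the space spanned by GR, PR and SF
$= \sum_j |x_j|$. In each box the *first LP* (`min_total_flux()`)
minimizes SF subject to the box; the reactions its solution leaves below
the flux threshold form the candidate $K$. Minimizing total flux is the
parsimonious-FBA heuristic: the candidate is the smallest active network
that realizes the box's phenotype, so everything else is proposed for
deletion.

## Why the SF axis matters

On the bundled seven-reaction network (`build_toy_network()`), every 2-D
grid cell over GR × PR has a minimum-flux solution that keeps the direct
growth route active, so validation always returns GR = 3, PR = 0 and the
grid search fails at every resolution. Constraining SF as a third axis
forces the minimum-flux vertex onto the capacity-limited alternative
route; the point cube GR = 1, PR = 2, SF = 13 isolates the coupled
vertex $(3,3,0,3,1,1,2)$ whose zero-flux reaction is exactly the correct
knockout.

## The dynamic refinement

`run_dyncubeprod()` computes the axis scales TMGR, TMPR, TMSF once, then
iterates levels $n = 0, 1, \dots, n_{max}$ with $P = 2^n$ divisions per
axis. Cube $(i,j,k)$ spans $[(i{-}1)\,\mathrm{TMGR}/P,\,
i\,\mathrm{TMGR}/P]$ on the growth axis, the analogue on the production
axis, and $[(k{-}1)\,2\,\mathrm{TMSF}/P,\, k\,2\,\mathrm{TMSF}/P]$ on the
SF axis — the SF axis deliberately spans twice its nominal scale so the
box certainly contains the polytope's SF range. Each of the 8 children
of a cube inherits the parent's feasibility flag as its explore mask
(`refine_mask()`): children of infeasible cubes are never solved, which
is sound because a subset of an empty set is empty. The scan runs in
ascending $(i, j, k)$ lexicographic order and stops at the first
accepted strategy, making the returned strategy a deterministic function
of the inputs.

Two design points here were genuinely open:

* **The root level.** The doubling schedule can start either at the
  whole space ($P=1$) or directly at 8 cubes with the root presumed
  feasible. The package examines the root explicitly by default
  (`include_root = TRUE`) so that its candidate is also validated; the
  presumed-feasible variant is available behind the flag and prunes
  identically thereafter.
* **Boundary membership.** Cube intervals are closed on both ends, so
  shared faces belong to both adjacent cubes. The harmless
  double-coverage buys a sharp guarantee: a vertex lying exactly on an
  SF level boundary (as the toy network's coupled vertex does, at
  SF = 13) is visible from both neighbouring cubes, and the high-SF
  neighbour is feasible — examining it is what lets the dynamic search
  find the toy's knockout already at $P = 2$.

## Axis scales

TMGR and TMPR are plain FBA maxima of growth and production over the
unmodified polytope. TMPR deliberately carries **no** growth floor: on
the toy network a floor of 1 would shrink TMPR from 3 to 2 and change
every printed interval. TMSF is made deterministic in two stages:
maximize PR subject to growth $\ge$ `min_growth`, then fix PR at that
optimum and maximize the split-component sum over the optimal face.
Reporting "SF at whichever vertex the PR-max LP returned" would be
solver-dependent; the face maximum is unique and a conservative cap.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_growth` | 1e-3 | minimum growth rate (flux units) an accepted strategy retains |
| `min_target` | 1e-3 | minimum guaranteed PR at maximal growth |
| `flux_epsilon` | 1e-5 | strict absolute threshold for "unused" reactions |
| `n_max` | 5 | finest level, $2^5 = 32$ divisions per axis |
| `protected` | roles | reactions never deleted |
| `gur`, `our`, `ngam` | 10, 1000/0, 3.15 | medium bounds (glucose, oxygen, ATP maintenance) |

The protected set defaults to every role reaction (growth, target,
uptakes, maintenance, auxiliary export): deleting the growth reaction
contradicts the objective, deleting the target removes the read-out, and
deleting medium reactions changes the experiment, not the strain. Only
the target exclusion is forced by the problem definition; the rest is a
package default and overridable.

## Numerical choices

* **LP backend.** All LPs run on a dense two-phase simplex with Bland's
  smallest-index pivoting (`dyncubeprod:::lp_solve`). The subdivision
  workload is dominated by *degenerate* instances — point intervals such
  as SF ∈ [13, 13], and optimal faces rather than unique vertices —
  so anti-cycling and determinism were the design criteria, not speed:
  Bland's rule guarantees termination, and a fixed pivot rule with fixed
  variable order guarantees that repeated runs return the identical
  vertex, which candidate extraction depends on. Tests cross-check the
  solver against an independent simplex implementation and against
  brute-force vertex enumeration.
* **Absolute values.** $\sum|x_j|$ is linearized by splitting reversible
  reactions into non-negative forward/backward components and summing
  components. For irreversible models this is exact. With reversible
  reactions a forced SF *lower* bound can be met by futile
  forward+backward activity — the standard LP-expressible relaxation of
  a non-convex constraint; the SF upper bound and the objective are
  unaffected.
* **Tolerances.** Pivot tolerance 1e-9; feasibility checks 1e-7;
  post-hoc assertions in tests 1e-6. Stage 2 of validation holds growth
  at `gr_max * (1 - 1e-6)` rather than exact equality, which is brittle
  in floating point. If stage 1 is infeasible (a pinned uptake that can
  no longer be consumed), validation returns the degenerate pair (0, 0)
  flagged `degenerate = TRUE` — callers only need "not acceptable".
* **Candidate threshold.** `flux_epsilon` is strict (`<`) and absolute,
  applied to $|x_j|$.

## What the random-network generator emulates

`generate_random_network()` draws irreversible, mass-balanced networks
built around a pinned uptake (bounds $[u, u]$, default $u = 10$), a
spanning chain that gives every metabolite a producer and a consumer, a
growth export at the chain's end, a target export on a random interior
metabolite, and random extra branch reactions. A third of the internal
reactions get a tight capacity cap drawn from $[0.1u, 1.2u]$ — the
bottlenecks that make re-routing, and hence growth coupling, possible.
The pinned uptake mirrors the demonstration network's fixed nutrient
input; with a free input the minimum-flux LP would return the zero flux
everywhere and every candidate would be the whole network.

These networks exercise the search machinery (pruning, parity between
static and dynamic scans, LP economy), but they do **not** emulate
genome-scale models: no reversible reactions in the generated set, no
cofactor coupling, no gene–protein–reaction structure, unit
stoichiometry only. Passing property tests therefore demonstrates
algorithmic correctness, not biological realism of the strategies.

Property tests run the searches on networks of 3–5 metabolites and 7–10
reactions through level $n = 3$ (up to 585 cubes per network), and the
pruning-soundness check re-solves every skipped cube directly on the toy
plus 50 seeded networks; vertex-enumeration oracles run on instances of
at most 8 reactions, where exhaustive basis enumeration is exact and
fast.

## Known limitations

* The dense simplex targets the small and medium models of the test
  scale; genome-scale models (thousands of reactions) parse fine via
  `read_model()` but the search would need an external industrial LP
  solver to be practical.
* `n_max` beyond ~5 multiplies cube counts by 8 per level; the dynamic
  pruning mitigates but does not remove the growth.
* Gene-level deletions, gap-filling and thermodynamic constraints are
  out of scope; deletions are per-reaction.
* With reversible reactions the SF lower bound is enforced on the
  component sum (see above), so a cube's "feasible" verdict can be
  conservative on networks with futile cycles.
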
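# dyncubeprod

Reaction-deletion (knockout) strategies for **growth-coupled production**
in constraint-based metabolic models, computed by dynamic subdivision of
the flux solution space.

## The problem

Flux balance analysis (FBA) models a metabolic network at steady state: a
flux vector `x` over the network's `n` reactions must satisfy `S x = 0`
(with `S` the stoichiometric matrix over the `m` internal metabolites) and
per-reaction bounds `LB <= x <= UB`. Two fluxes matter for strain design:
the growth rate GR (flux of the biomass reaction) and the production rate
PR (flux of the target-metabolite export). A knockout set `K` — reactions
forced to zero flux — achieves *growth coupling* when, with `K` deleted,
the cell's maximal-growth behaviour necessarily produces the target:

```
maximize GR  subject to  S x = 0,  x_j = 0 for j in K,  LB <= x <= UB
accept K  iff  GR >= GR_min  and  min PR at maximal GR >= PR_min
```

Finding such a `K` by bilevel optimization (OptKnock-style) is
exponential in practice. The subdivision family instead scans boxes of
the solution space spanned by three axes — GR, PR, and SF, the total
absolute flux `sum(|x|)` — and in each box:

1. **first LP** — minimize `sum(|x|)` inside the box; if infeasible, the
   box is empty;
2. collect the candidate `K = { j : |x_j| < 1e-5 }` (minus protected
   reactions) from the minimum-flux vertex;
3. **second LP** — validate `K` without box constraints: maximize GR with
   `K` deleted, then minimize PR with GR fixed at its maximum;
4. accept if both thresholds hold.

Three search drivers are provided:

* `run_gridprod()` — a 2-D grid over GR x PR (no SF constraint);
* `run_cubeprod()` — a static 3-D scan of all `P^3` cubes at fixed `P`
  divisions per axis (axis scales TMGR, TMPR, 2·TMSF);
* `run_dyncubeprod()` — the dynamic variant: start with the whole space,
  double `P` each level, **skip every cube whose parent was infeasible**
  (a sub-space of an empty space is empty), and stop at the first
  accepted strategy.

The SF axis is what makes the 3-D searches strictly stronger than the
grid: constraining total flux forces the minimum-flux vertex onto
alternative routes that the growth pathway would otherwise shadow.

## Worked example

```r
library(dyncubeprod)

toy <- build_toy_network()     # 7 reactions, 4 internal metabolites
compute_theoretical_maxima(toy, min_growth = 1)
#> theoretical maxima: TMGR = 3, TMPR = 3, TMSF = 13

res <- run_dyncubeprod(toy, search_params(min_growth = 1, min_target = 1))
res
#> deletion strategy: R3
#>   GR = 1, PR = 2, ACCEPTED
#>   found at P = 2, cube (1, 2, 2)
#>   total LPs solved: 17
```

Deleting `R3` closes the direct route to the growth precursor; growth
must then run through the capacity-limited bypass `R5` (GR = 1), and mass
balance forces the remaining input — a production flux of PR = 2 —
through the target export. The same network defeats the 2-D grid search
at every resolution (`run_gridprod()` returns no accepted strategy):
without the SF axis, every grid cell's minimum-flux solution keeps the
direct growth route active and validation collapses to GR = 3, PR = 0.

A command-line front end is installed at
`system.file("cli", "dyncubeprod.R", package = "dyncubeprod")` with
`design`, `batch` and `fixture` subcommands.

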
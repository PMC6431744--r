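# optcoupleR

Growth-coupled strain design for genome-scale metabolic models: joint
optimization of gene (reaction) knockouts, heterologous reaction insertions
and growth-medium supplements.

## The problem

Production of a chemical by a microbial cell factory is easiest to improve by
adaptive laboratory evolution when production is *growth-coupled* — when any
fast-growing mutant is necessarily also a producing one. optcoupleR searches
for combinations of modifications that create such coupling, quantified by
the **growth-coupling potential**

```
U = f̂(M) − f̂(M*)
```

where `f̂(M)` is the maximal growth rate of the modified model `M` (flux
balance analysis with the biomass reaction as objective) and `f̂(M*)` the
maximal growth rate of the same model with the target production reaction
blocked. Production is (weakly) growth-coupled exactly when `U > 0`:
non-producers then grow strictly slower than producers.

Maximizing `U` over designs is naturally a bi-level program — an outer search
over binary modification variables `y` with two inner FBA maximizations.
optcoupleR collapses it to a single-level MILP by replacing the inner
`max f(M*)` with its LP dual (weak duality makes any dual-feasible point an
upper bound, and the outer maximization drives it onto the optimum):

```
max_{y, v, λ, μ}   f(M) − f(M*_D)
s.t.               S v = 0,  lb_j y_j ≤ v_j ≤ ub_j y_j      (primal half)
                   Sᵀλ + μᵁ − μᴸ = c,  μ ≥ 0               (dual half of M*)
                   z = y·μ linearized with big-M rows
                   Σ_KO (1 − y) ≤ K_ko,  Σ_INS y ≤ K_ins,  Σ_SUP y ≤ K_sup
```

Binary `y_j = 1` means "reaction usable": knockout candidates are native
reactions, insertion candidates come from a universal reaction pool pruned by
metabolite reachability, and supplement candidates are exchange reactions
whose uptake opens when enabled. Around the solver sit the workflow steps:
solution-pool harvesting (native-style no-good cuts), reduction of each
design to a minimal coupled set, merging of equivalent designs, verification
by direct simulation, and production-envelope analysis.

LPs and MILPs are solved with the HiGHS solver through SciPy (a `python`
with `scipy` must be on the `PATH`; see `inst/python/lp_backend.py`).

## Worked example

The bundled supplement fixture is a five-metabolite network in which biomass
needs two precursors; knocking out the native bypass creates an auxotrophy
that only supplement X can relieve — through a pathway that co-produces the
target compound.

```r
library(optcoupleR)

fx <- toy_supplement_network()
model <- file.path(tempdir(), "toy.json")
write_model(fx$network, model)

res <- cmd_run(model, "DM_P", "out/", config = fx$config,
               max_knockouts = 1, max_supplements = 1, supplements = "X_e")
#> [optcouple] step 1: loading model /tmp/.../toy.json
#> [optcouple] step 2: assembling MILP (3 KO, 0 INS, 1 SUP candidates)
#> [optcouple] step 3: solving (seed 1, 1 run(s))
#> [optcouple] step 3: status optimal, best objective 5, pool size 2
#> [optcouple] step 4: reducing, merging and verifying 2 design(s)
res$exit_code
#> [1] 0
```

`out/designs.tsv` then contains the single verified minimal design:

```
design_id  knockouts  insertions  supplements  U  growth  min_production  yield
design_1   RBy                    EX_X         5  5       4.999995        0.5
```

Read: knock out the bypass `RBy` and feed supplement X (`EX_X` opened to
uptake). The strain then grows at 5 /h, any growth-optimal flux state
produces at least ~5 mmol/gDW/h of the target (yield 0.5 mol per mol carbon
source), and blocking production costs the cell its entire growth rate
(`U = 5` /h) — a strongly selectable coupling. `envelope_design_1.csv` holds
the production envelope (min/max target flux versus growth rate).

The same functions scale to genome-scale models: `load_model()` reads SBML
(fbc) or COBRA JSON, `knockout_candidates()`, `load_universal_pool()` /
`prune_universal_pool()` and `supplement_candidates()` build the design
space, and `verify_design()` / `production_envelope()` evaluate any design —
e.g. the propionate designs of the iJO1366 *E. coli* reconstruction (see the
acceptance tests). A shell front end is installed as `exec/optcouple`
(`run`, `verify`, `envelope` subcommands).

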
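---
title: "Growth-coupled strain design with optcoupleR: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled strain design with optcoupleR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optcoupleR)
```

## The objective: growth-coupling potential

optcoupleR designs production strains whose growth *requires* production.
The quantity it maximizes is the growth-coupling potential

$$U = \hat f(M) - \hat f(M^*),$$

the loss in maximal growth rate (1/h, by flux balance analysis) incurred when
the target reaction is blocked. Under the weak notion of coupling — optimal
growth implies non-zero production — a design is coupled exactly when
$U > \varepsilon$, and $U$ is also the selection advantage producers hold
over non-producers in an adaptive-evolution experiment: a large $U$ makes
coupled strains easy to evolve. An alternative objective used by related
knockout-design methods is the minimum production at optimal growth; it also
certifies coupling but can leave the growth-rate gap between producers and
non-producers marginal. `verify_design()` reports both, and asserts their
equivalence at the $\varepsilon$ threshold on every call.

The method inherits all assumptions of constraint-based metabolic modeling:
steady state ($Sv = 0$), flux bounds as the only capacity limits, growth as
the cellular objective, and no regulation, thermodynamics or toxicity. A
design that is coupled in silico can be uncoupled in vivo by enzymes missing
from the reconstruction, and conversely reactions carried by the model but
repressed in vivo can make designs look infeasible; predicted designs are
candidates for manual curation, not guarantees.

## From bi-level to single level

Maximizing $U$ over designs is bi-level: an outer binary search over
modifications $y$, with $\hat f(M)$ and $\hat f(M^*)$ themselves
maximizations. Because $\hat f(M^*)$ enters with a negative sign, replacing
the inner problem by its LP dual gives an exact single-level reduction: any
dual-feasible point over-estimates $\hat f(M^*)$ (weak duality), and the
outer maximization of $f(M) - f(M^*_D)$ presses the dual half down onto the
true optimum (strong duality) while pressing the primal half up onto
$\hat f(M)$. At any fixed admissible $y$ the optimum of the single-level
problem therefore equals $U(y)$ exactly.

Mechanically (`dualize()`, `assemble_optcouple()`):

* variable bounds are lifted into explicit rows before dualization, so every
  bound owns a dual multiplier $\mu^U_j, \mu^L_j \ge 0$ — the handles through
  which the binaries act on the dual half;
* one shared binary per controlled reaction, orientation $y_j = 1$ =
  "usable". In the primal half it couples fluxes
  ($lb_j y_j \le v_j \le ub_j y_j$; supplements couple only the uptake
  bound). In the dual half the bound terms of the dual objective become
  products $y_j \mu_j$, each replaced by an auxiliary $z_j$ with the standard
  big-M rows $z \le My$, $z \le \mu$, $z \ge \mu - M(1-y)$, $z \ge 0$ (the
  two $\pm My$ rows of the general four-row pattern collapse because
  $\mu \ge 0$);
* knockouts are counted as $\sum_{KO}(1 - y) \le K_{ko}$, insertions and
  supplements as plain sums.

Binaries act on *reactions*, not genes: that is how the coupling constraints
are formulated, and it keeps the MILP clean. Mapping knocked-out reactions
back to gene sets through GPR rules is a reporting concern, deliberately out
of the optimization.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `carbon_uptake_bound` | 10 | mmol/gDW/h | standard aerobic glucose minimal-medium cap |
| `oxygen_uptake_bound` | 1000 | mmol/gDW/h | effectively unconstrained aeration |
| `supplement_uptake_bound` | 10 | mmol/gDW/h | uptake opened per enabled supplement; no community convention exists, so the knob is prominent |
| `coupling_epsilon` | 1e-6 | 1/h | growth-rate noise floor defining "coupled"; far below biological growth rates, far above LP tolerance |
| `big_M` | 1000 | — | dual-multiplier box and linearization constant; equals the conventional finite surrogate for open flux bounds |
| `pool_time_factor` | 10 | — | harvest budget as a multiple of the first solve's time |
| `time_limit_s` | 600 | s | desk-scale cap per solve; cluster-scale caps are configuration, not defaults |

Infinite bounds are replaced by ±1000 mmol/gDW/h on load — the same
magnitude as the conventional open bound in genome-scale reconstructions, so
the surrogate is not an extra modeling decision.

## Design space construction

*Knockouts*: native internal reactions, minus biomass, targets, boundary
reactions, user exclusions and ATP maintenance — recognised by id prefix
`ATPM` or by a strictly positive lower bound, since a forced flux can never
be removed without making the model infeasible.

*Insertions*: any model-like JSON pool is accepted. Entries colliding with
native ids are dropped and stoichiometric duplicates (up to positive
scaling) deduplicated. Pruning then runs one round per allowed insertion: a
pool reaction is admitted when every metabolite it can *consume* (all
metabolites, for reversible reactions) is native or producible by previously
admitted pool reactions. Constraining only the consumable side is a
deliberate superset of stricter all-metabolite matching: a reaction whose
novel product is consumed by a later insertion is a perfectly feasible
two-step pathway, and a pruning step — being purely a performance filter —
must never exclude a feasible insertion. Metabolites are matched by id after
compartment normalization; whether pool compartments should be remapped onto
host compartments is model-curation territory the package does not enter.

*Supplements*: a manual metabolite list (default: fructose, lactate, acetate
and the 20 proteinogenic L-amino acids; "lactate" is mapped to D-lactate,
the *E. coli* fermentation product, and the list is user-overridable) is
resolved to exchange reactions. Enabling a supplement opens uptake to
`-supplement_uptake_bound`; secretion bounds are untouched. Supplement
exchanges are closed to uptake by `apply_medium()` before any optimization,
so the binary is the only way in.

The target is a demand reaction added by `add_target_demand()`; for targets
like propionate the cytosolic species is drained by default (the
conventional compartment for demand reactions), with the compartment and the
state of any native exchange left as explicit user choices.

## Solving, pools and post-processing

The MILP is solved by HiGHS (through SciPy). After the first solve, further
integer solutions are harvested with no-good cuts
$\sum_{y^*_j = 0} y_j + \sum_{y^*_j = 1}(1 - y_j) \ge 1$ for
`pool_time_factor` times the first solve's wall time, stopping at
`pool_max` solutions or when objectives fall to $\varepsilon$. Multiple
seeded runs under permuted variable order can be united (`n_runs`), since
MILP solvers reach different near-optimal solutions from different
orderings.

Every harvested assignment is then re-simulated exactly by two LP solves.
This is not cosmetic: at binary values within the solver's integrality
tolerance of 1 the big-M rows leak up to $M \cdot 10^{-6}$ per term, which
can fabricate a spurious potential of order $10^{-3}$. Reported objectives
are always the re-simulated values; entries whose MILP objective deviated by
more than $10^{-5}$ carry a `flagged` field and a message.

Post-processing mirrors the workflow's last step: `reduce_design()` removes
modifications one at a time (deterministic order: knockouts, insertions,
supplements, each sorted — different orders can reach different minimal
sets, so the order is fixed and documented) until no single removal
preserves coupling; `merge_designs()` deduplicates on set equality and ranks
by $U$, then minimum production, then lexicographically;
`verify_design()` fixes growth into the band
$\mu \ge (1 - 10^{-6})\,\mu_{max}$ — a relative band rather than an equality,
to avoid degeneracy at the optimal vertex — and minimizes/maximizes target
flux. The reported "production rate" is the *minimum* target flux at optimal
growth (the quantity that certifies weak coupling; the maximum is reported
alongside), and yield divides it by the realized carbon uptake at that
optimum, not by the uptake bound.

## Numerical choices

* LP/MILP solves: HiGHS defaults (primal/dual feasibility ~1e-9); all
  package-level equality assertions use 1e-6; MILP-vs-simulation agreement
  uses 1e-5.
* Infeasible FBA (e.g. a lethal knockout with forced maintenance flux)
  returns growth 0 with an `infeasible` flag instead of erroring — knockout
  enumeration legitimately produces lethal designs and $U$ must stay
  evaluable. A model feasible at zero flux simply reports optimum 0.
* $U$ is clamped at 0: $M^*$ is a restriction of $M$, so negative values can
  only be solver noise (warned above $10^{-5}$).
* Dual multipliers are boxed at `big_M`. The box truncates the dual cone; a
  multiplier at its box means the dual half may under-report $U$, which the
  exact re-simulation of pool entries catches.
* Equal-objective designs are ordered lexicographically by sorted
  modification ids, making reports reproducible across runs.

## What the synthetic fixtures emulate — and what they do not

The three generator networks are authored, not random: random stoichiometries
essentially never exhibit clean growth-coupling, and auditable fixtures must
have hand-solvable optima (small integer coefficients keep the LP solutions
exact).

* `toy_knockout_network()` (5 metabolites, 5 reactions + target demand): a
  bypass knockout makes production obligatory. Documented optimum
  {KO `R2`}, $U = 10$.
* `toy_insertion_network()`: coupling requires knocking out a native bypass
  *and* inserting heterologous `H1`; the second pool entry is removed by
  single-insertion pruning. Documented optimum {KO `RBy`, insert `H1`},
  $U = 10$.
* `toy_supplement_network()`: a knockout-induced auxotrophy is relieved only
  by a supplement, through a production-forcing pathway; the supplement alone
  does not couple because the relief route offers no growth advantage while
  the bypass stands. Documented optimum {KO `RBy`, supplement `EX_X`},
  $U = 5$.

They exercise every mechanism of the MILP (knockout, insertion and
supplement binaries, pruning, pools, reduction) at sizes where exhaustive
enumeration is the ground truth — 16 candidate modifications or fewer. What
they do not emulate is what makes genome-scale search hard: thousands of
binaries, degenerate alternate optima, cofactor coupling across
compartments, and solve times measured in hours. A passing fixture suite
shows the formulation and machinery are correct, not that every genome-scale
run will close its MIP gap within a desk-scale time limit. As a
deterministic genome-scale check, the test suite evaluates two published
three-knockout propionate designs on the iJO1366 *E. coli* reconstruction
(six LP solves); full genome-scale *searches* are cluster-scale and are
exercised here only in fixture-sized shape.

Problem sizes used by the tests and the acceptance script: fixture MILPs
with 2–4 binaries and ~30–45 rows; 50 random LPs of 12 variables × 8 rows
for duality; 17 enumerated designs for the exhaustive coupling and
minimality checks.

## Known limitations

* Reaction-level binaries: designs requiring the distinction between
  isozymes or gene-level interventions need GPR post-processing.
* One binary per reaction governs both directions of a reversible reaction;
  direction-specific knockouts are not expressible.
* The dual-multiplier box (`big_M`) trades exactness for backend-agnostic
  linearity; pathological models needing larger multipliers must raise it.
* No production-pathway prediction: the target reaction (and any heterologous
  production route) is supplied by the user, and the pool ships as data.
* Medium design is limited to opening uptakes from a candidate list;
  substitution of the primary carbon source is not searched.
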
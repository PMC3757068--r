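# fluximba — flux imbalance analysis of constraint-based metabolic models

Flux balance analysis (FBA) predicts steady-state reaction fluxes in a
metabolic network by linear programming:

```
maximize  c'v    subject to    S v = b,    v_LB <= v <= v_UB
```

with `S` the m×n stoichiometric matrix and `b = 0` encoding steady
state. This package is about the *dual* side of that calculation. Every
steady-state constraint carries a dual variable — the **shadow price**
`lambda_i = dZ*/db_i` of metabolite *i* — measuring how the optimum
responds to a *flux imbalance* (net accumulation `b_i > 0` or depletion
`b_i < 0`) at that metabolite. Under growth maximization, a negative
shadow price marks a **growth-limiting** metabolite: allowing extra
outflow from it raises the maximal growth rate. The same machinery
applied to an expression-integration LP (GIMME/TEAM-style inconsistency
minimization) turns shadow prices into predictions of whether a
metabolite's abundance should rise or fall.

The package is aimed at systems-biology researchers who work with
constraint-based models and want the sensitivity information that
solvers usually discard: dual values, reduced costs, validity ranges,
and brute-force validation of all of it.

## What it provides

* **Model core** — a `metabolic_model` container (sparse S, bounds,
  objective, right-hand side, Boolean gene–protein–reaction rules),
  readers/writers for SBML Level 3 + FBC v2, a JSON dialect and a
  simple TSV dialect, medium application (COBRA sign convention), and
  in-silico gene knockouts via GPR evaluation.
* **LP duality** — `solve_fba()` returns primal fluxes *and* shadow
  prices, reduced costs and the dual objective; `build_dual()`
  constructs the explicit dual program so strong duality can be
  verified independently; `shadow_price_table()` adds the validity
  range `[G-, G+]` of every shadow price from LP ranging.
* **Degeneracy checking** — `incremental_shadow_price()` /
  `decremental_shadow_price()` recompute each sensitivity by fresh
  perturbed re-solves (`b_i = p*G+` or `p*G-`, default `p = 0.2`);
  `check_degeneracy()` flags metabolites whose one-sided sensitivities
  disagree with the solver's dual value — the signature of alternate
  dual optima.
* **Expression integration** — per-gene quantile penalty thresholds
  (default θ = 0.88), penalties `max(0, x_g − EXP_g)`, OR→min/AND→max
  propagation to reactions, a required-metabolic-functionality bound
  (default 30% of the FBA maximum), the inconsistency-score LP with
  magnitude-penalized reversible fluxes, and the sign rule mapping its
  shadow prices to predicted abundance directions.
* **Statistics** — coefficient of variation of post-perturbation time
  courses (30-minute window), the quadrant permutation test linking
  shadow prices to temporal variation, the Matthews correlation
  coefficient with a permutation p-value, and paired
  Spearman/Pearson association reports.
* **Fixtures** — deterministic toy networks with analytically derived
  ground truths (including a constructed degenerate optimum) and
  seeded generators for synthetic expression matrices and metabolite
  time courses.
* **CLI** — `inst/scripts/fluximba` with subcommands `fba`,
  `shadow-prices`, `check-degeneracy`, `team`, `dynamics`, `synth`,
  `report`.

The LP engine is a self-contained bounded-variable two-phase simplex
(`simplex_lp()`) that exposes the optimal basis, duals, reduced costs
and right-hand-side ranging — the quantities this package exists to
analyze.

## A worked example

The canonical one-metabolite network: an uptake reaction (capacity 10)
produces `M`, an objective drain (capacity 1000) consumes it.

```r
library(fluximba)
fx  <- make_fixture("figure1")
sol <- solve_fba(fx$model)
sol
#> FBA solution: status = optimal, Z = 10
shadow_price_table(fx$model, sol)
#>   metabolite_id compartment lambda range_low range_high valid
#> 1          M[c]           c     -1      -990         10  TRUE
```

`Z = 10`: the uptake cap is the bottleneck. `lambda = -1`: each unit of
extra outflow from `M` (`b < 0`) raises the optimum by one — `M` is
growth-limiting — and the price is valid for imbalances in
`[-990, 10]`, set by the drain and uptake caps respectively.

On a network built to have alternate dual optima (two drains with
different objective weights), the brute-force check exposes the
degeneracy that a single solver call would hide:

```r
check_degeneracy(make_fixture("degenerate")$model)
#>   metabolite_id lambda_solver lambda_plus lambda_minus range_high range_low   p
#> 1          M[c]            -1          -1         -0.5          5     -1000 0.2
#>   degenerate
#> 1       TRUE
```

Accumulation costs 1 per unit (`lambda+ = -1`) but depletion is only
worth 0.5 (`lambda- = -0.5`): the sensitivity genuinely depends on the
direction of the imbalance, and the metabolite is flagged.

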
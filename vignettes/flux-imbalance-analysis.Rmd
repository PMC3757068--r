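---
title: "Flux imbalance analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux imbalance analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluximba)
```

## The model and what its dual means

Flux balance analysis (FBA) predicts steady-state reaction rates in a
stoichiometric network by solving the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = b, \qquad
v^{LB} \le v \le v^{UB},$$

where $S$ is the $m \times n$ stoichiometric matrix, $b$ the vector of
per-metabolite accumulation/depletion rates (zero at steady state), and
$c$ the objective weights (typically the biomass reaction). This
package's subject is not the primal solution but the **dual** one. Each
steady-state row carries a dual variable $\lambda_i$ -- the *shadow
price* of metabolite $i$ -- with the sign convention

$$\lambda_i = \frac{\partial Z^*}{\partial b_i},$$

the marginal change of the optimal objective per unit of *flux
imbalance* at metabolite $i$ ($b_i > 0$: net accumulation, $b_i < 0$:
net depletion). Under growth maximization a negative $\lambda_i$ means
that letting the network drain metabolite $i$ would raise the maximal
growth rate: the metabolite is *growth-limiting*. The explicit dual
program built by `build_dual()` is

$$\min_{\lambda,\,\mu^{LB},\,\mu^{UB} \ge 0} \;
b^\top \lambda + v^{UB\top}\mu^{UB} - v^{LB\top}\mu^{LB}
\quad \text{s.t.} \quad
S^\top \lambda + \mu^{UB} - \mu^{LB} = c,$$

with $\mu^{LB}, \mu^{UB}$ the multipliers of the flux bounds (the
reduced costs). Strong duality makes its optimum equal the primal $Z$,
which the test suite verifies by solving both programs independently on
randomized networks.

Shadow prices are only defined up to the geometry of the feasible
polytope: each $\lambda_i$ is valid on an interval
$[G^-_i, G^+_i]$ of perturbations of $b_i$, beyond which the optimal
basis changes. `shadow_price_table()` reports these ranges from
classical LP ranging on the optimal basis, and records with a range
narrower than `eps_range` ($10^{-6}$ by default) are marked invalid and
should be discarded; the default matches the package-wide numerical
tolerance, and nearby values ($10^{-3}$ to $10^{-6}$) give the same
qualitative classifications on the bundled fixtures.

## The LP engine

No LP solver with a dual/ranging interface is part of this package's
dependency footprint, and the dual information *is* the scientific
payload here, so the package carries its own solver: a dense, two-phase
bounded-variable primal simplex (`simplex_lp()`) using Bland's rule
(hence guaranteed finite) with fully recomputed basis inverses at every
iteration. This favours numerical transparency over speed and is
entirely adequate for the package's scale -- fixtures and curated
networks of up to a few hundred reactions; it is not intended to race
interior-point codes on genome-scale models, though it solves them
correctly given time. The solver exposes the optimal basis, duals,
reduced costs and right-hand-side ranging, which is exactly the surface
the rest of the package consumes. During development its optima and
equality duals were cross-checked against an independent HiGHS
implementation on randomized instances; one frozen instance ships in
the test suite.

## Degenerate shadow prices and the brute-force check

At a degenerate optimum the dual solution need not be unique: the
one-sided marginal values of a constraint can differ, and a solver
reports an essentially arbitrary member of the optimal dual face. The
package validates every shadow price by brute force:

* $\lambda^+_i$: re-solve with $b_i = p \cdot G^+_i$ and divide the
  objective change by the perturbation actually applied;
* $\lambda^-_i$: the mirror image with $b_i = p \cdot G^-_i$.

The fraction defaults to $p = 0.2$; because the perturbation stays
inside the validity range, any $p \in (0,1)$ gives identical values on
nondegenerate instances (the suite checks $p \in \{0.2, 0.5, 0.9\}$).
When only one direction admits a perturbation, only that side is
recalculated and the other is reported as absent (`NA`), never as zero.
A disagreement between $\lambda^\pm$ and the solver's value beyond
`tolerance` (default $10^{-6}$, ten times the solver feasibility
tolerance) flags the metabolite as degenerate.

One subtlety: basis ranging can report a zero-width range on one side
of a degenerate vertex even though the optimal-value function
$Z(b_i)$ is still linear there. `check_degeneracy()` therefore locates
the true first breakpoint of $Z(b_i)$ on each side by fresh re-solves
(a certified step from the basis range, then doubling and bisection).
This keeps the check backend-independent: it never trusts the dual
information it is trying to validate. Perturbed problems are solved
from scratch, not warm-started, so a carried-over basis cannot mask a
degeneracy. Ranges are probed out to a cap of $10^6$ flux units, far
beyond any bound in the bundled networks.

The constructed `degenerate` fixture shows the mechanism: one producer
($\le 5$) and two drains with objective weights 1 ($\le 5$) and 0.5
(large cap). Accumulation removes weight-1 flux ($\lambda^+ = -1$)
while depletion routes through the weight-0.5 drain
($\lambda^- = -0.5$); a solver may legitimately report either value,
and the check flags the disagreement.

## Expression integration and its shadow prices

The integration LP replaces growth maximization with the minimization
of an inconsistency score between fluxes and expression data:

$$\min_v \; IS = \sum_j c_j |v_j| \quad \text{s.t.} \quad
S v = b, \quad v^{LB} \le v \le v^{UB}, \quad v_{RMF} \ge v_{RMF,min}.$$

* **Thresholds.** Each gene's penalty threshold $x_g$ is the
  $\theta$-quantile of that gene's own measurements pooled over all
  samples (default $\theta = 0.88$). Quantiles interpolate linearly
  between order statistics so that thresholds -- and everything
  downstream -- move continuously in `theta_scan()`. Pooling all
  columns of the matrix is the package's choice; replicate-aware
  pooling would be a preprocessing step upstream.
* **Gene penalties.** $p_g = \max(0, x_g - EXP_g)$: no penalty at or
  above threshold, otherwise the shortfall.
* **Reaction penalties.** Rules propagate by OR $\to$ min (any
  isozyme suffices) and AND $\to$ max (a complex is limited by its
  least-expressed member). The mapping is checked against a
  truth-table oracle that enumerates all satisfying gene subsets.
  Genes without expression data contribute no penalty (no evidence, no
  penalty).
* **Absolute flux.** The objective is linear only after splitting each
  reaction into nonnegative forward/reverse halves that both carry the
  penalty, so reversible flux is penalized by magnitude in either
  direction rather than rewarded for running backwards.
* **RMF.** The required-functionality bound is a fraction (default
  0.3) of the plain-FBA maximum of the RMF flux, and an unreachable
  RMF (maximum 0) is an error, because the constraint exists precisely
  to exclude the trivial all-zero solution.

The shadow prices of this minimization, $\lambda_i = \partial
IS^*/\partial b_i$, are reported unmodified, which preserves the sign
rule: a *positive* value means that draining metabolite $i$ would
lower the inconsistency, so its abundance is predicted to *decrease*;
negative predicts an increase; `predict_direction()` applies a
$10^{-6}$ dead-band around zero.

## The statistical layer

**Temporal variation** of a metabolite after a perturbation is the
coefficient of variation (sample standard deviation over mean) of the
measurements within a 30-minute window. The $n-1$ estimator is used
because the time courses are short; a labeled $t = 0$ baseline is
included by default and can be dropped with `include_t0 = FALSE`.
Zero-mean windows leave the CV undefined and the metabolite is
excluded downstream.

**The quadrant permutation test** asks whether metabolites avoid the
combination of strongly negative shadow price ($\lambda < m_S$) and
large temporal variation ($CV > m_T$), with $m_S$ the center (mean or
median) of the $\lambda$ values and $m_T$ that of the CV values. The
observed count in that forbidden quadrant is compared against random
re-pairings of the two vectors ($10^5$ by default, seeded). Two
conventions are implemented for the p-value: the strict count
$P(p_i < p_{orig})$, which is the package default, and the inclusive
$P(p_i \le p_{orig})$. On discrete quadrant counts the strict variant
is anti-conservative (simulated null rejection near 8--9% at nominal
5% for 60 metabolites) while the inclusive variant is valid (near
3--4%); the calibration checks in the test suite and acceptance script
therefore evaluate the inclusive variant, and analyses that need
guaranteed type-I control should set `strict = FALSE`. The test is
invariant to monotone rescaling of CV when the median center is used.

**MCC.** Shadow-price sign as a binary classifier is scored with the
Matthews correlation coefficient; since no analytic null is assumed,
its p-value is a label permutation (two-sided on $|MCC|$, add-one
corrected, seeded), consistent with the quadrant test.

## Synthetic data: what it emulates and what it does not

The `branched` generator draws linear pathways with parallel isozyme
stages and pairwise-distinct random capacities (resampled until all
stage capacities differ by more than 0.05, so no accidental ties create
degeneracy), for which $Z$ and every shadow price follow analytically
from bottleneck analysis; the generator's truths are derived from that
analysis, never from the solver under test. The expression generator
makes active-pathway genes peak in the query sample and inactive genes
dip there, emulating the phase structure of a periodic transcriptome;
the time-course generator draws each metabolite's trajectory around a
constant baseline with a target CV that, in signal mode, is low
(0.02--0.15) for negative-shadow-price metabolites and broad
(0.05--0.9) otherwise, and in null mode is broad for everyone. The
default study size for the statistical checks is 60 metabolites (30
limiting, 30 neutral), 7 time points over 30 minutes, 200 null
datasets at $10^4$ permutations and 50 signal datasets -- sizes chosen
so the whole calibration is a desk-scale computation.

These generators are deliberately idealized: real metabolomics time
courses have measurement error correlated across metabolites,
non-constant baselines, and CVs that are not assigned by the sign of a
model quantity; real transcriptomes are not bimodal switches. Passing
tests on these fixtures demonstrates that the *machinery* (duality,
ranging, degeneracy detection, penalty propagation, test calibration)
is correct, not that the biological claims hold on any particular
organism's data -- reproducing those requires genome-scale
reconstructions and published datasets fed through
`scripts/reproduce_knockouts.R` and the regular API, with the medium
supplied explicitly (published media formulations do not map uniquely
onto exchange bounds, so the mapping is deliberately an input, not a
constant).

## Numerical choices and limitations

* Package-wide tolerance $10^{-6}$ for validity ranges, degeneracy
  comparison and direction dead-bands; solver pivot tolerance
  $10^{-9}$ and feasibility tolerance $10^{-7}$.
* Knockouts zero a reaction's bounds instead of deleting the column,
  so metabolite/reaction indices stay aligned across strains and
  differential shadow-price tables (`delta_shadow_prices()`) need no
  re-matching.
* Exchange reactions are identified structurally (a column touching
  exactly one metabolite); media follow the convention negative flux =
  uptake. Exchanges absent from a medium get their uptake closed and
  their secretion left open.
* Unbounded primals are reported as a status, with no dual extraction;
  infeasibility is likewise a status, annotated when knocked-out
  reactions are present (the signature of a lethal deletion).
* The simplex recomputes dense basis inverses; beyond a few thousand
  reactions this becomes the bottleneck and a factorization-updating
  or external solver backend would be the natural extension point
  (`simplex_lp()` is the single choke point to swap).
* Positive shadow prices under growth maximization are reported under
  their own label by `classify_growth_limiting()` rather than forced
  into the limiting/non-limiting dichotomy, which is defined for
  negative and zero values.

## A worked example

```{r example}
fx <- make_fixture("figure1")
sol <- solve_fba(fx$model)
sol$objective_value
shadow_price_table(fx$model, sol)
check_degeneracy(fx$model)
```

The drain cap (1000) limits how much extra outflow the metabolite can
absorb ($G^- = -990$) and the uptake cap (10) limits accumulation
($G^+ = 10$); within that window the optimum moves one-for-one against
the imbalance ($\lambda = -1$), and the brute-force recalculations
agree with the solver from both sides, so nothing is flagged.
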
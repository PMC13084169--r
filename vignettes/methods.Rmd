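---
title: "Methods: knockout flux variability analysis with fluxko"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockout flux variability analysis with fluxko}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fluxko)
```

# Scope

fluxko predicts the metabolic consequences of deleting a single gene in
a constraint-based (stoichiometric) metabolic model. The workflow is:

1. load a model (SBML Level 3 with the FBC version 2 extension, or the
   package's JSON dialect),
2. evaluate each reaction's gene–protein–reaction (GPR) boolean rule
   under the deletion and close the bounds of reactions whose rule
   evaluates false,
3. compare wild-type and knockout models by flux balance analysis (FBA)
   and flux variability analysis (FVA),
4. classify reactions by the change in their attainable flux range,
5. flag metabolites predicted to accumulate because every reaction able
   to consume them is active in the wild type but blocked in the
   knockout.

This vignette documents the mathematical conventions, the default
parameters and the reasoning behind them, and the design of the
synthetic validation networks.

# Model and linear programs

A model is a stoichiometric matrix $S \in \mathbb{R}^{m \times n}$
($m$ metabolites, $n$ reactions), flux bounds
$l, u \in \mathbb{R}^n$, and a designated objective reaction (typically
a biomass pseudo-reaction). All analyses assume steady state,
$S v = 0$.

**FBA** solves

$$\max_v \; v_{\mathrm{obj}} \quad \text{s.t.}\quad S v = 0,\; l \le v \le u.$$

**FVA** first computes the FBA optimum $Z^\*$, then for each reaction
$j$ solves two further LPs,

$$\min_v / \max_v \; v_j \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,\; v_{\mathrm{obj}} \ge f \, Z^\*,$$

where $f \in [0, 1]$ is the *optimality fraction*. At $f = 0$ the
objective floor is dropped entirely. The resulting interval
$[v_j^{\min}, v_j^{\max}]$ is the reaction's attainable flux range; a
reaction whose range is $\{0\}$ within tolerance is *blocked*.

The LPs are solved by a built-in bounded-variable two-phase primal
simplex (`lp_solve()`). No external solver is required; the
implementation handles equality and inequality rows, finite or
infinite variable bounds, and reports `optimal`, `infeasible` or
`unbounded`. Its endpoints are validated in the test suite against
brute-force vertex enumeration on small integer-bound networks.

# Knockout simulation and the range-change statistic

`apply_knockout(model, gene)` evaluates every reaction's GPR rule with
the gene deleted (`rule_active()`); "and" denotes an enzyme complex
(all genes required), "or" denotes isozymes (any gene suffices), and
"and" binds tighter than "or". Reactions whose rule evaluates false
have both bounds set to zero. Reactions with an empty rule are never
disabled.

For each reaction the perturbation statistic is the summed absolute
change of the FVA endpoints between knockout (KO) and wild type (WT):

$$\Delta\mathrm{range}_j \;=\; \bigl|\,v^{\max}_{j,\mathrm{KO}} - v^{\max}_{j,\mathrm{WT}}\,\bigr| \;+\; \bigl|\,v^{\min}_{j,\mathrm{KO}} - v^{\min}_{j,\mathrm{WT}}\,\bigr|.$$

A reaction is *affected* when $\Delta\mathrm{range}_j$ exceeds the
significance threshold (default 1.0 flux units). Because alternative
optima can make FVA endpoints numerically fragile, every
above-threshold reaction is re-tested at a tightened feasibility
tolerance (default $10^{-10}$); reactions whose recomputed
$\Delta\mathrm{range}$ falls back under the threshold are labelled
`numerical_noise` and excluded. `knockout_analysis()` wraps this whole
sequence and also reports the affected set's subsystem distribution.

# Sensitivity analysis

Two sweeps probe robustness of the conclusions:

* `capacity_curve(model, reaction, fractions)` traces a reaction's
  maximal flux as the optimality fraction varies. Curves must be
  non-increasing in $f$ (a tighter objective floor can only shrink the
  feasible set); the function asserts this.
* `threshold_robustness(model, gene, fractions)` recomputes the
  affected-reaction set at several fractions (default
  $\{0.9, 0.75, 0.5\}$) and reports whether the sets are identical,
  plus the symmetric differences when they are not.

The default working fraction is $f = 0.9$: high enough to restrict
analysis to near-optimal growth states, low enough to leave slack for
secondary pathways to show their capacity.

# Accumulation (reporter-metabolite) analysis

A reaction *can consume* metabolite $i$ given flux ranges when it can
carry flux that removes $i$: stoichiometric coefficient $s_{ij} < 0$
with $v_j^{\max} > \tau$, or $s_{ij} > 0$ with $v_j^{\min} < -\tau$
(a reversible producer running backwards). The blocked/active
tolerance is $\tau = 10^{-6}$.

`find_accumulating()` flags metabolite $i$ as a candidate for
accumulation when its WT consumer set is non-empty and **every** WT
consumer is blocked in the KO (range inside $[-\tau, \tau]$). The
scope is either the metabolites touching affected reactions
(`"affected_universe"`, the default) or all metabolites (`"all"`).
`compartment_summary()` tabulates candidates per compartment with
integer-rounded percentages.

# Synthetic networks with analytic ground truth

`generate_synthetic_model(synthetic_spec(...))` builds a small network
whose correct analysis results are known in closed form, used
throughout the test suite and the acceptance script.

The design is a shared-resource trade-off. A single resource enters
through an exchange reaction capped at `resource_budget` $B$
(default 100). A biomass reaction consumes `biomass_yield` $y$
(default 1) resource per unit flux, so the growth optimum is $B / y$.
A degradation chain of `chain_length` $L$ gated steps (all carrying
the GPR gene `G_FOCAL`, default $L = 3$) converts a polymer through
$L - 1$ intermediates into an end product; each step consumes
`degradation_cost`$/L$ resource per unit flux, so a full traversal
costs `degradation_cost` $c$ (default 1) in total and the chain's
maximal flux at optimality fraction $f$ is

$$\mathrm{cap}(f) = \frac{B\,(1 - f)}{c}.$$

Splitting the cost evenly across steps keeps this formula exact for
every individual gated step, which is what `capacity_curve()` is
checked against.

Ground truth under the `G_FOCAL` knockout:

* growth is unchanged (the chain only competes for leftover resource),
* the affected set is the gated chain plus, when no alternative route
  exists, the polymer source and end-product sink,
* the accumulating set is every chain metabolite (polymer head,
  intermediates, end product) — all their consumers are gated.

With `bypass = TRUE` a non-gated shortcut converts the polymer head
directly to the end product. It survives the knockout, so the polymer
head and end product keep active consumers and only the interior
intermediates accumulate; the source and sink also drop out of the
affected set. This exercises the accumulation rule's specificity (no
false positives from metabolites with surviving consumers).

`n_decoys` adds independent exchange/consumption reaction pairs that
never interact with the chain; they pad the network without touching
the ground truth. The `seed` shuffles presentation only — reaction
ordering and decoy identifiers — never the analytic answers, and the
generator restores the caller's RNG state afterwards.

These toys deliberately do **not** imitate a genome-scale model's size
(thousands of reactions), its degree distribution, or its nested
isozyme/complex GPR rules; they isolate the logic of each analysis
step at a scale where the correct answer is provable. Typical suite
problem sizes are 3–20 reactions; the LP engine itself has no such
limit.

# Tolerances

| constant | default | used for |
|---|---|---|
| feasibility tolerance | $10^{-9}$ | simplex pivoting / status decisions |
| noise re-test tolerance | $10^{-10}$ | re-solving above-threshold reactions |
| blocked/active tolerance | $10^{-6}$ | blocked ranges, consumer activity |
| significance threshold | $1.0$ | $\Delta\mathrm{range}$ classification |

The significance threshold of 1.0 flux units is a practical cut
separating structural capacity changes from degenerate-optimum
wobble; `threshold_robustness()` is the tool for checking that
conclusions do not hinge on it.

# Worked example

```{r example}
gen <- generate_synthetic_model(synthetic_spec(chain_length = 3,
                                               n_decoys = 2, seed = 7))
res <- knockout_analysis(gen$model, "G_FOCAL", fraction = 0.9)
res
sort(res$affected)
identical(sort(res$affected), sort(gen$truth$expected_affected))
```

The full report bundle (growth, capacity, range, robustness and
accumulation tables plus a JSON manifest) is produced by
`run_full_analysis(analysis_config(...))`, or from the shell via the
script in `system.file("cli/fluxko.R", package = "fluxko")`.

# Limitations

* FVA endpoints, not flux samples: the analysis characterizes
  attainable ranges, never a unique flux distribution.
* Accumulation candidates are qualitative flags derived from blocked
  consumption; no kinetics or concentrations are modelled.
* The simplex is dense and single-threaded; genome-scale sweeps
  (tens of thousands of LPs) work but are slow compared to dedicated
  sparse LP solvers.
* SBML support targets Level 3 + FBC v2 with explicit per-reaction
  bound parameters; Level 2 documents and kinetic constructs are
  rejected rather than approximated.
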
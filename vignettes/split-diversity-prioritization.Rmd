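---
title: "Split diversity and exact conservation prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split diversity and exact conservation prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitdiv)
```

## The diversity model

A split σ is a bipartition of a fixed, ordered taxon set
X = {s₁, …, sₙ}, encoded as a binary vector; the vector and its
complement denote the same bipartition, so `splitdiv` stores the canonical
orientation in which the first taxon carries 0. A split system (Σ, λ)
attaches a non-negative weight λ(σ), in branch-length units, to each
split. The split diversity of a subset S is

SD(S) = Σ λ(σ) over the splits that *separate* S, i.e. have at least one
member of S on each side.

Every edge of an unrooted tree induces a split whose weight is the branch
length; consequently SD over a single tree's split system equals Faith's
(unrooted) PD, which `pd_score()` computes independently by subtree
extraction. This identity is the package's most important internal check
and is tested exhaustively over all subsets of small random trees. Trivial
splits (one taxon versus the rest) are always retained: they carry the
pendant branch lengths, are required for the PD identity, and make a 100%
SD target equivalent to covering every taxon.

Rooted input trees are implicitly unrooted. The two root-incident edges
induce the same bipartition; extraction merges them by summing lengths, the
same rule used for duplicate split lines in NEXUS input. Branch lengths
absent from a Newick string become 0 with a warning rather than an error,
so topology-only bootstrap files remain usable with frequency weighting.

### Pooling tree collections

`aggregate_trees()` supports three weighting conventions:

* **mean** (default): λ(σ) is the average branch length over all trees,
  counting 0 where a tree lacks the split. SD is then an expectation of PD
  over the tree collection, which is the natural reading when the trees
  are bootstrap replicates or posterior samples.
* **sum**: unnormalized pooled lengths.
* **frequency**: the fraction of trees containing the split (weights in
  [0, 1]), for topology-only collections.

The choice is exposed because published split systems differ in
convention; mean-with-zeros is the default for the expectation argument
above. Similarly, reported *relative* SD can use the total weight of all
splits (default) or of non-trivial splits only — both conventions occur in
the literature, so `relative_sd()` takes a `denominator` argument.

## The optimization problems

All three problems are formulated as 0/1 integer linear programs over
area variables xᵢ or taxon variables vᵢ, split variables y_σ, and (for
the boundary term) adjacency variables z_ij.

**Reserve selection.** Minimize
Σ cᵢxᵢ + β(Σ bᵢᵢxᵢ − 2Σ b_ij z_ij) subject to Σ λ(σ) y_σ ≥ (p/100) Σ λ(σ).
The boundary (fencing) objective is the linearization of the quadratic
perimeter expression: z_ij ≤ xᵢ and z_ij ≤ x_j suffice because z_ij has a
negative objective coefficient in a minimization, so the solver pushes it
to its upper bound; the lower bound z_ij ≥ xᵢ + x_j − 1 is redundant and
only emitted under `strict_z = TRUE`. Each split variable is bounded above
by the number of selected areas covering each of its sides, so y_σ = 1
certifies that both sides of the bipartition are covered. Since the y
variables are only bounded above, a solver may legally leave some y at 0
even when the split separates the covered taxa; reported solutions
therefore recompute SD and the per-split indicators from the presence
matrix, never from the raw y values, and assert the target is met.

**Taxon selection.** Maximize Σ λ(σ) y_σ subject to Σ vᵢ ≤ k, the same
split bounds over v, and per non-basal taxon j either
v_j ≤ Σ_{i∈C_j} vᵢ (plain viability: at least one prey) or
Σ_{i∈C_j} w_ji vᵢ ≥ (d/100) v_j (diet viability). Forced taxa are fixed
at 1 and count toward k by default (`forced_exempt` flips this),
matching the reading that a set "containing 10% of the taxa" includes its
forced members.

### Numerical choices

* **Exact p% thresholds.** By default split weights are scaled by 10⁶ and
  rounded, and the right-hand side becomes the smallest integer not below
  (p/100)·Σλ′ (`sd_threshold()`). Both the ILP builder and the
  enumeration oracle call the same helper, so "at least 95% of SD" can
  never be lost to floating-point dust, and ILP-versus-oracle comparisons
  are exact.
* **Diet constraints are scaled by 100/d** so their coefficients are O(1)
  in units of the threshold. Without this, a solver's absolute feasibility
  tolerance could blur arbitrarily small d; with it, the reduction of
  d%-viability to plain viability at d = ε holds exactly. The predicate
  `is_d_viable()` mirrors this with a slack *relative* to d/100 (default
  10⁻⁹), so a predator with no selected prey fails for every d > 0.
* **ε for the d → 0⁺ reduction** is fixed at 10⁻⁷ (i.e. `d = 1e-7`),
  comfortably below any realistic diet proportion and far above the
  relative slack.
* **Ties.** Only objective values are guaranteed; distinct optimal sets
  may exist. A deterministic post-pass (`solve_ilp_lex()`,
  `lexicographic = TRUE` in the solvers) selects the lexicographically
  smallest optimal 0/1 vector — which prefers *excluding*
  earlier-indexed areas/taxa — by iterative re-solving; it is off by
  default because it multiplies the solve count.
* **Degenerate inputs.** Splits with an uncoverable side are reported and
  force y = 0 (they may be harmless below the target p); p = 100 with an
  uncoverable taxon is declared infeasible up front with the taxa named;
  an infeasible forced set yields a certificate naming the predator and
  its missing prey; SD of the empty set and singletons is 0; PD of
  subsets smaller than 2 is 0 with a warning.

### The solver

Models are held in a solver-agnostic form (`ilp_model()`), exportable in
LP format. Exact solves go through the HiGHS branch-and-bound code via
`scipy.optimize.milp` in a batched Python subprocess; batching matters
because interpreter start-up dominates the sub-millisecond solve time of
the validation-scale models. Every `optimal` assignment is re-verified
against the constraints in R before it is accepted, and infeasibility is
reported as a status, never as an empty optimum. Independently of the
solver, `brute_force_reserve()` and `brute_force_taxon()` enumerate all
subsets (up to 15 areas / 20 taxa) against the plain predicates; the test
suite and the acceptance script compare the two routes on hundreds of
seeded instances.

## Food webs

Arrows point from predator to prey; taxa without prey are basal. Although
the viability model is motivated by acyclic webs, the constraints are
purely local, so webs with cycles (omnivory loops are common in real
data) are accepted with a warning; `strict_dag = TRUE` rejects them.
`validate_web()` also reports diet rows that do not sum to 1, taxa
unreachable from any basal taxon, and — given d — predators whose total
in-web diet is below d/100 and are therefore unselectable. Diet scores
are raw sums over the web's listed prey; prey consumed outside the web
can be acknowledged with a constant `base_credit` added to every
predator's score (default 0).

## The synthetic-instance generators

The generators define the conditions under which the package validates
itself; all are deterministic functions of the seed.

* **Tree collections** (`gen_tree_collection()`): a base tree with random
  topology and exponential branch lengths, perturbed per replicate by
  `nni_moves` random NNI moves and multiplicative lognormal length jitter
  (σ = 0.2 by default) — emulating bootstrap variation. Defaults: 10
  trees, 1 NNI move.
* **Landscapes** (`gen_landscape()`): g × g unit cells, 4-neighborhood
  boundary matrix (shared edges 1, perimeter 4), rectangular clustered
  ranges of linear extent ~`range_frac`·g (non-empty by construction),
  integer unit-price costs (1–5), and an urban corner block
  (`urban_frac`·g per side).
* **Food webs** (`gen_foodweb()`): taxa spread over `n_layers` trophic
  layers, arrows only from higher to strictly lower layers (acyclic by
  construction, ≥ 1 prey per consumer, density set by `connectance`),
  diet rows from a symmetric Dirichlet (concentration 1 = uniform
  simplex) summing to 1 exactly.

Validation problem sizes are chosen so enumeration stays exact: reserve
instances use 8 areas and 6–10 taxa (2⁸ subsets), taxon instances 8–12
taxa with k ∈ 3–8, 200 seeded instances per problem family, and the PD–SD
identity is checked exhaustively on 50 trees of 4–8 taxa. The
economic-pressure analysis uses a 4 × 4 grid whose urban block is a 2 × 2
corner; the instance is required to satisfy the study condition that the
ratio-1 optimum uses the urban block while rural areas alone can attain
the target — the configuration in which economic pressure is actually
informative. The ratio grid runs in steps of 0.5 up to the point where
any urban-holding set is provably dominated.

What these instances do *not* emulate: realistic biogeography (ranges are
axis-aligned rectangles), allometric food-web structure, non-treelike
signal beyond NNI noise, or empirical cost surfaces. Passing tests
demonstrate the correctness of the formulations and solver contract under
these controlled conditions, not the ecological fidelity of any
particular planning instance.

## Economic-pressure analysis

`cost_ratio_sweep()` scales urban unit prices by a ratio ρ and re-solves;
because the optimum is the lower envelope of finitely many linear cost
lines (intercept: rural cost + β·fence; slope: base urban cost of the
set), the minimal cost is concave piecewise-linear in ρ, and consecutive
ratios with the same optimal set merge into intervals carrying their exact
line. `accumulated_cost_crossover()` compares two candidate sets under a
rising ratio trajectory: the default discrete mode sums per-step costs
over the grid; the analytic mode solves the accumulated-cost equality in
closed form (the positive root of a quadratic in the step index on a
uniform grid). The two agree within one grid step by construction; both
are provided because the discrete sum matches a year-by-year budgeting
reading, while the closed form is grid-free.

## Known limitations

* Solver access requires a Python interpreter with SciPy ≥ 1.9 on the
  PATH; there is no in-R fallback solver (the enumeration oracles are for
  validation, not production scale).
* Only bottom-up food-web dependencies are modeled — no top-down effects,
  mutualism, seasonal or abundance constraints.
* The lexicographic tie-break re-solves once per variable and is not
  intended for large instances.
* Cost lines in sweeps assume urban scaling acts multiplicatively on the
  per-area cost; heterogeneous cost indices must be baked into `cost`
  beforehand.
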
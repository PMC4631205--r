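---
title: "Constraint-based modelling of gut-microbiota effects on host metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of gut-microbiota effects on host metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

# The modelling problem

Germ-free and conventionally raised animals differ systematically in amino
acid, glutathione and lipid metabolism. Genome-scale metabolic models
(GEMs) let those differences be interrogated mechanistically: a GEM is a
stoichiometric network with flux bounds and gene-reaction (GPR) rules, and
flux balance analysis (FBA) predicts steady-state flux distributions as
solutions of the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

where $S$ is the stoichiometric matrix and $c$ selects an objective flux
(here, secretion of a lipoprotein pseudo-metabolite). This package
implements the full analysis chain around that LP: integration of relative
differential expression into condition-specific bounds (RMetD),
flux-space sampling with transcriptional-regulation calls, ensemble
comparison of model collections, a diet-partitioned two-species gut
community simulation, and reporter-metabolite statistics — all exercised
on seeded synthetic fixtures so that every claim in the test suite is
reproducible offline.

# Flux analysis primitives

`fba()` maximises the objective; `pfba()` then minimises total absolute
flux $\sum_i |v_i|$ at a fixed fraction of that optimum by splitting every
reaction into non-negative forward and backward parts, which is exact for
LPs; `fva()` reports the attainable $[\min, \max]$ flux per reaction
(two LPs each), optionally with the objective floored.

All three sit on a bounded-variable primal simplex written for this
package (`solve_bounded_lp()`): a two-phase method with explicit variable
bounds and Bland's smallest-index pivoting rule, which cannot cycle. The
problems solved here are small and dense (tens of reactions), so the basis
is refactorised at every iteration; numerical robustness on degenerate
polytopes — fixed variables, forced uptake windows — was the design
priority, not speed. Feasibility is accepted at $10^{-6}$, pivot
tolerances are $10^{-9}$, and every optimal solution is checked in tests
to satisfy $\lVert S v\rVert_\infty < 10^{-6}$. Unbounded directions
cannot arise in practice because all model variables carry finite default
bounds of $\pm 1000$ mmol/gDW/h.

# RMetD: relative expression to condition-specific bounds

RMetD ("relative metabolic differences") converts *relative* expression
changes between two conditions into flux-bound changes, rather than
mapping absolute expression onto fluxes. The procedure in `run_rmetd()`:

1. Apply diet uptake limits to a reference copy and a condition copy.
2. For each objective product (chylomicron first, then HDL), maximise it
   alone and set its secretion lower bound to 20% of that maximum
   (`product_floor_fraction`, default 0.20) in both copies.
3. Project the DE table onto reactions: a reaction is *up* if all its
   significant genes (Q < 0.05) are up, *down* if all are down, and
   *unchanged* when they disagree — mixed trends are deliberately treated
   as no significant change.
4. Run FVA over the mapped reactions in the reference copy with the
   product floors active. The primary objective is *not* fixed at its
   optimum here: fixing it would collapse exactly the ranges the scaling
   is meant to act on, and only the product floors are imposed before
   variability is measured.
5. Impose the FVA ranges as hard bounds on the reference copy; on the
   condition copy impose the scaled ranges — multiply both ends by
   $1+\alpha$ for up-regulated and $1-\alpha$ for down-regulated reactions
   (default $\alpha = 0.20$). Multiplying both ends means a signed
   interval like $[-5, 10]$ expands away from zero ($[-6, 12]$) under
   up-regulation and shrinks toward zero under down-regulation, which
   preserves reversibility and matches the intended reading of "able to
   carry more/less flux".
6. Optionally clamp scaled bounds back inside the original model bounds
   (`cap_at_model_bounds`). The cap protects against scaling a reaction
   beyond its physical capacity; it is switched off in the synthetic study
   because the enterocyte toy forces its luminal uptakes into narrow
   windows, and clamping would pin the condition model to those windows.
7. Solve both copies by parsimonious FBA maximising the primary product;
   secondary products are read out of the same parsimonious solution
   rather than optimised separately.
8. Report per-product secretion fluxes and condition/reference ratios.

Infeasibility at step 7 is never silently repaired: an elastic re-solve
minimises the total violation of the imposed bounds and reports which
reactions must give, attached to the result as a diagnostic.
`sensitivity_scan()` repeats the whole procedure over a set of $\alpha$
values and flags whether the sign of every product difference is stable —
the synthetic study checks $\alpha \in \{0.1, 0.2, 0.3\}$.

With an empty DE table the two copies are identical and every product
ratio is 1; this identity, the exact 20% floor, the exact multiplicative
scaling, and the property that all-down regulation can never raise the
achievable product maximum are all asserted in the test suite.

# Flux sampling and regulated-reaction calls

`sample_fluxes()` draws flux vectors by artificial-centering hit-and-run:
warmup LP vertices (per-coordinate extrema first, then random objective
directions, 200 by default) define the polytope's extent; the walk then
moves along directions through the running centre, entirely inside the
null space of $S$, keeping every 10th point (default) until `n` samples
(default 5000) are collected. Drift off the steady-state subspace is
re-projected away every 200 steps. The sampler is a pure function of the
seed — two runs with the same seed are bitwise identical — and a polytope
that is a single point (every flux determined) is detected from the warmup
vertices and returned as replicated columns with zero spread.

`call_regulated()` compares two sample sets: a reaction's flux direction
is *up*/*down* when its means are separated by more than
`separation` $\times(\sigma_{ref}+\sigma_{cond})$ (default multiple 1.0),
and the direction itself is judged on the flux *magnitude*, so an uptake
(negative flux) that becomes less negative counts as down-regulated.
A reaction is *transcriptionally regulated* when this flux direction is
non-null and concordant with its expression direction. The separation
rule is a documented stand-in: the original methodology names no numeric
criterion, so the multiple is exposed in the configuration rather than
hidden.

# Ensemble comparison

`pairwise_distances()` computes, per model pair, the Hamming distance
between element sets — the number of element changes needed to transform
one model into the other — decomposed into the two directed counts
$|A\setminus B|$ and $|B\setminus A|$ (always reported as an ordered,
labelled pair, since prose descriptions of such counts are ambiguous
about orientation). `heterogeneity()` summarises an ensemble as mean
pairwise distance over maximum pairwise distance, a dimensionless degree
in $[0,1]$ (0 when all models coincide); this is the only dimensionless
combination of exactly the average and maximum Hamming distance, but the
formula is an interpretation and is flagged as such. `core_statistics()`
counts union, core (present in all models) and unique (present in exactly
one) elements, with the core percentage rounded to one decimal. Distances
are raw counts, never normalised by union size.

# Community simulation

`partition_diet()` splits the daily diet by nutrient class: by default
bacteria may take at most 40% of protein and digestible carbohydrate and
5% of non-digestible carbohydrate; 5% of protein and digestible
carbohydrate passes to the colon; the small intestine receives the
remainder, including all fat. Protein is expanded into amino acids by a
weight-fraction profile, and grams become mmol through explicit molar
masses — there is no internal lookup table, so unit errors surface as
missing-molar-mass errors rather than silent misconversions.

`simulate_community()` runs a round-robin scheme on the bacterial pool:
at the start of each round, every member's demand for every pool
metabolite is probed by an FVA maximum-uptake query with the full pool on
offer, and contested metabolites are allocated proportionally to demand
(proportional sharing is order-free within a round; the member order only
matters through cross-feeding, and is documented as the input order).
Each member then maximises its biomass by FBA with uptake bounds set to
its allocation, fluxes are fixed by parsimonious FBA, and secretions
enter the pool of the next round. Iteration stops when all growth values
change by less than the tolerance ($10^{-6}$ by default) or after
`max_rounds` (20), in which case the result is flagged unconverged with
its growth trace. Amounts are mmol per simulated day at unit biomass; no
dynamic biomass integration is attempted. The per-metabolite ledger
(pool, allocated, consumed, cross-fed, residual) closes to $10^{-6}$ by
construction and is re-checked in tests.

# Reporter metabolites and validation statistics

`reporter_metabolites()` aggregates gene-level p-values onto metabolites
through network topology: the neighbour genes of a metabolite are the
genes in the GPRs of the reactions touching it; each p-value becomes
$z = \Phi^{-1}(1-p)$ (p clamped into $[10^{-15}, 1-10^{-15}]$ to keep z
finite); a metabolite with $k$ neighbours scores
$z_{raw} = \sum z/\sqrt{k}$, corrected against the mean and standard
deviation of 10,000 seeded random size-$k$ gene draws. Scoring is
two-sided (unsigned), matching the classical reporter formulation.
Under null (uniform) gene scores the corrected values are approximately
standard normal, which the suite checks on a 50-gene toy network.
`greedy_reporter_subnetwork()` grows a connected metabolite set from the
best scorer, accepting additions that keep the mean score level (so
plateaus of equally scored metabolites are traversed) and stopping on a
strict drop, ties broken lexicographically; on a 10-metabolite pathway
with a planted stretch it provably matches exhaustive search over
connected subsets.

`welch_test()` and `bh_fdr()` wrap the standard Welch unequal-variance
t-test and Benjamini-Hochberg step-up adjustment; both are verified in
tests against hand-computed closed forms, and `compare_groups()` applies
them per analyte of a (log-transformed) two-group panel.
`merge_segment_de()` integrates per-segment DE tables by lowest Q-value
and drops genes significant in opposite directions in different segments.

# Synthetic data: what it emulates and what it does not

The generators stand in for inputs that would otherwise require large
external downloads (deposited mouse and bacterial GEMs, microarray
series, diet supplements):

* `make_toy_gem()` emits flux-consistent toy models with analytically
  known optima. The `epithelium` template is an enterocyte caricature —
  forced luminal uptake windows (glucose 9–10, fat-derived lipid 4.5–5,
  amino acids 1.8–2 mmol/day), a glutathione synthesis chain, and
  chylomicron/HDL assembly, with genes on every step including the
  transporters. Forced windows keep internal fluxes tightly determined,
  so bound scaling shifts sampled flux means measurably; that is a
  deliberate idealisation — real tissue GEMs have far wider flux ranges,
  so regulated-reaction recall on real data would be lower than on this
  fixture.
* `make_de_table()` plants up/down regulation at chosen fractions with
  Q-values straddling the 0.05 threshold and returns the implied
  reaction-direction truth for recovery tests.
* `make_crossfeed_pair()` builds a glucose fermenter secreting acetate
  and an acetate-consuming butyrate producer plus a four-class chow-like
  diet (protein with amino-acid profile, digestible and non-digestible
  carbohydrate, fat) in realistic daily gram amounts.
* `make_metabolomics()` draws log-normal two-group panels with specified
  log-scale effects; effect 2 (natural-log units) at n = 6 per group has
  essentially full power, while effect 0 calibrates the type-I error.

All generators consume an isolated RNG stream, so they neither disturb
nor depend on the caller's random state. What passing tests show is that
the algorithms implement their definitions and recover planted structure
under the stated noise; they do not show that the biological conclusions
transfer to any particular real dataset.

# Problem sizes and numerical choices

The suite runs on models of 3–14 reactions, sample sets of 200–10,000
points, 1,000-analyte null panels, and 2,000–10,000 background draws for
reporter correction — sizes chosen so the whole analysis replays in a few
minutes on one CPU while keeping every statistical check well-powered.
Ties in greedy expansion break lexicographically; contested-nutrient
allocation is proportional to probed demand; product ratios with a zero
reference and zero condition are defined as 1 (and infinite when only the
reference is zero). Degenerate inputs (empty DE tables, empty pools,
constant measurement groups, single-point flux polytopes) are exercised
explicitly in tests.

# Known limitations

* The SBML reader/writer covers Level 3 Version 1 with the
  flux-balance-constraints (fbc v2) annotations as written by this
  package and by common constraint-based tools; exotic SBML features
  (species references by id groups, kinetic laws) are ignored.
* The simplex is dense and refactorises every iteration; it is meant for
  toy-to-small models, not genome-scale matrices with thousands of
  reactions.
* Hit-and-run sampling has no mixing guarantee on badly conditioned
  polytopes; the tests check calibration only on the fixture geometries.
* The community scheme is steady-state with proportional sharing; it does
  not model dynamic biomass, spatial structure, or more than the trivial
  n-member extension of the round-robin.
* The regulated-reaction separation rule and the heterogeneity-degree
  formula are documented interpretations of methods whose originals give
  no explicit numeric criterion.
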
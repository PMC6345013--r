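---
title: "Constraint-based modeling of stilbene biosynthesis with stilflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of stilbene biosynthesis with stilflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stilflux)
library(dplyr)
```

`stilflux` is a toolkit for building, curating and interrogating
genome-scale metabolic models (GSMMs) of secondary-metabolite-producing
fungi, organized around stilbene (resveratrol) biosynthesis. This
vignette explains the models and procedures the package implements, the
assumptions they rest on, the tunable parameters and their defaults, and
the design choices made where several defensible options existed.

## The constraint-based model

A metabolic model is a compartmentalized reaction network: metabolites
carry an elemental formula (Hill notation) and a formal charge,
reactions carry a signed stoichiometry, flux bounds in mmol/gDW/h, a
gene–protein–reaction (GPR) boolean rule, and a kind (metabolic,
transport, exchange, sink/demand, biomass, spontaneous). Flux balance
analysis (FBA) treats the cell as a steady-state flow network: given the
stoichiometric matrix $S$ (metabolites × reactions), it solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

usually with the biomass pseudo-reaction as objective, whose flux is the
specific growth rate $\mu$ (h$^{-1}$). The steady-state assumption means
no metabolite accumulates; everything consumed is produced, with
boundary (exchange, sink, demand) reactions supplying or draining
material. Uptake follows the convention of a negative lower bound on an
exchange: `set_medium()` first closes every exchange for uptake, then
opens the listed nutrients at their maximum rates, and opens "unlimited"
species (water, protons, minerals) at 1000 mmol/gDW/h — large enough to
be non-binding.

Default bounds are $(-1000, 1000)$ for reversible and $(0, 1000)$ for
irreversible reactions, matching the conventional ±1000 mmol/gDW/h
treatment of effectively unbounded fluxes.

### The LP core

No linear-programming package is assumed: FBA, flux variability analysis
(FVA) and robustness scans run on a built-in bounded-variable two-phase
primal simplex (`solve_lp()`). Bland's rule is used for entering and
leaving variables, so the method cannot cycle and is fully
deterministic; the basis system is re-factorized every iteration, which
is numerically conservative and entirely adequate at mini-network sizes
(~100 reactions; solves take tens of milliseconds). Feasibility and
optimality tolerances are $10^{-9}$, below any quantity asserted by the
tests; reported fluxes below $10^{-6}$ in magnitude are clamped to zero,
since values beyond that precision are solver noise. Degenerate optima
are treated as a fact of life: the optimal *objective* is the contract,
and individual fluxes are only ever asserted through FVA ranges. The
test suite cross-checks LP objectives against an independent backend
(scipy's HiGHS, driven through a small JSON bridge) to $10^{-6}$.

### MOMA

Minimization of metabolic adjustment predicts the immediate flux state
of a perturbed network as the closest feasible state to a wild-type
reference: $\min \sum_j (v_j - v_{\mathrm{ref},j})^2$ subject to the
perturbed constraints, over **all** reactions (exchanges included, the
standard quadratic formulation). The QP is strictly convex, so the
minimizer is unique. Implementation detail worth knowing: the equality
block ($Sv = 0$ plus any pinned fluxes) is eliminated by an SVD-based
null-space reduction before the active-set solve (quadprog). Handing
quadprog ~90 equality rows directly is numerically fragile — with the
reference itself feasible the optimum sits on dozens of degenerate
ties — whereas the reduced problem has ~15 free dimensions, an identity
Hessian, and only box constraints. A phase-1 LP feasibility check runs
first so that an infeasible perturbation is reported as such rather than
mis-solved, and a perturbation that leaves the reference feasible
returns it exactly (distance 0).

## Biomass assembly

The biomass pseudo-reaction drains monomers in dry-weight proportion:
monomer $m$ of macromolecule $M$ gets coefficient
$f_M \cdot w_m / \mathrm{MW}_m$ (mmol/gDW), with $f_M$ the macromolecular
mass fraction (g/gDW), $w_m$ the monomer's mass fraction within $M$, and
$\mathrm{MW}_m$ its molar mass in g/mmol. By construction the drained
monomer mass closes to 1 g/gDW (enforced to $10^{-6}$). The bundled
composition uses 32% cell wall, 20% protein, 15% mannitol, 15% ash, 14%
lipid and 4% nucleic acid. DNA monomer mole fractions follow genome GC
content ($\mathrm{dGMP}=\mathrm{dCMP}=\mathrm{GC}/2$, the rest split
between dAMP/dTMP; default GC 50.96%), converted to mass fractions via
the dNMP molar masses.

Two maintenance terms capture ATP costs not tied to stoichiometry:
growth-associated maintenance (GAM, default 60 mmol ATP/gDW) enters the
biomass reaction as an ATP-hydrolysis term, and non-growth-associated
maintenance (NGAM, default 1.0 mmol ATP/gDW/h) is a lower bound on a
standing hydrolysis reaction (`ATPM`). Both defaults are assumptions in
the range typical of filamentous fungi — the source composition data do
not pin them numerically — and both are plain arguments to
`composition_fixture()`. Raising GAM can only lower the attainable
growth rate (a property the tests verify); NGAM beyond the achievable
ATP turnover renders the model infeasible, which is reported, not
masked.

Ash is a non-elemental pseudo-species (empty formula, molar mass
assigned as 0.1 g/mmol) supplied by a sink and excluded from balance
checking; mannitol is treated as a freely drained cytosolic storage
compound.

## Curation: balance checking and duplicates

`check_balance()` computes per-element and charge residuals for every
reaction. Exchange, sink, demand and biomass reactions are skipped by
convention (they are deliberately unbalanced drains), as is any reaction
touching a metabolite with an unknown formula. The checker reports
residuals; it never auto-corrects, because the proton/charge convention
of a third-party model is a modeling decision, not an error to fix
silently. One convention choice ripples through the bundled network:
diphosphate is modeled fully deprotonated (P2O7^4−), under which the
acetate-activating reaction `g0770`
(`ac[c] + coa[c] + atp[c] -> h[c] + accoa[c] + ppi[c] + amp[c]`)
balances exactly as written.

`find_duplicate_reactions()` canonicalizes stoichiometries (metabolites
sorted by id, coefficients divided by the first, rounded to 10
significant digits) so that scaled copies and reactions written in the
reversed direction land in the same group; groups mixing directions or
reversibilities are flagged as conflicts for manual resolution.
Coefficients are double-precision throughout — R has no exact rational
type in the supported stack — and the 10-digit rounding makes duplicate
detection robust to representation noise while still far below any
chemically meaningful coefficient difference.

## Draft reconstruction and gap filling

`filter_orthologs()` applies the inclusive thresholds identity ≥ 40%
and e-value ≤ 1e−30 to BLAST-like hit tables; the mapping is one-way
(no reciprocal-best filter), matching the plain protein-similarity
criterion. `draft_from_references()` imports a reference reaction iff
its GPR is satisfiable when exactly the mapped subject genes are
present, rewrites GPRs into query gene ids (multi-mapped subjects become
OR alternatives), and merges cross-reference duplicates by the canonical
key, flagging reversibility disagreements in the draft report rather
than resolving them silently.

`gap_fill()` restores a required function (e.g. growth on rhamnose) by
adding candidates from a universal reaction set. The procedure is
deliberately LP-only and deterministic: add all candidates, verify the
target is attainable, then prune in the candidates' given order,
removing each reaction whose absence still leaves the objective above
the threshold. The result is minimal in the sense that removing any
returned reaction breaks the target. When even the full set cannot
restore the objective, the result lists blocked biomass precursors
(objective substrates with zero attainable production), which is the
actionable diagnostic a curator needs.

## Perturbation analyses

`single_gene_deletion()` disables, per gene, every reaction whose GPR
becomes unsatisfiable, re-solves FBA, and calls the gene essential when
knockout growth falls below 1% of wild type. The 1% threshold is a
robustness choice — comfortably above LP round-off, far below any
biologically meaningful residual growth — and is configurable; the same
growth-call threshold style applies in phenotype tests ($\mu > 10^{-6}$
h$^{-1}$ ⇒ growth). The screen is order-independent and is verified in
the tests against a delete-and-re-solve enumeration on the independent
backend.

`scan_overexpression_targets()` reproduces the in-silico search for
product-enhancing targets: solve the wild type with the product exchange
lower-bounded (default 0.001 mmol/gDW/h), then force each reaction with
non-zero wild-type flux to `fold` times that flux (default 2, following
the observed twofold product response of the stilbene-pathway genes) and
evaluate the product rate. Two evaluations are offered, and the
difference is scientifically meaningful:

* `method = "moma"` (default) reports the product flux of the
  minimal-adjustment state — the immediate response. On the bundled
  network the forced stilbene-pathway surplus partly spreads into the
  pterostilbene/piceatannol side branches, because splitting a flux
  across parallel disposal routes always lowers a quadratic distance;
  4CL and CHS are still ranked among the improving targets.
* `method = "fba"` is a lexicographic capability evaluation: growth is
  re-maximized under the forced bound, then the product exchange is
  maximized at that growth. This measures what the overexpressed strain
  *can* deliver and is the reading under which forcing twice the
  wild-type flux through 4CL or CHS yields exactly a twofold product
  increase.

## The synthetic mini-network

`mini_model()` builds a deterministic ~100-reaction, two-compartment
(cytosol/extracellular) network carrying the full topology the analyses
need: glucose, sucrose, rhamnose and ethanol uptake; glycolysis
(including PFK) and gluconeogenesis; the oxidative and non-oxidative
pentose phosphate pathway producing erythrose 4-phosphate; the complete
shikimate chain to chorismate and prephenate; tyrosine and phenylalanine
synthesis; the phenylpropanoid route (PTAL tyrosine/phenylalanine
ammonia-lyase, C4H, 4CL); malonyl-CoA synthesis (ACC) and a fatty-acid
drain; a CHS assigned the stilbene-synthase role (3 malonyl-CoA +
p-coumaroyl-CoA → resveratrol + 4 CO2 + 4 CoA, the canonical
stilbene-synthase stoichiometry) beside a naringenin-chalcone branch
from the same substrates, embodying the CHS/STS functional overlap;
resveratrol O-methylation (pterostilbene) and hydroxylation
(piceatannol) side branches; the ethanol assimilation route ending in
the acetate activation `g0770`; a TCA sketch supplying
2-oxoglutarate → glutamate; lumped respiration (P/O 2.5) and a
transhydrogenase; and the biomass reaction from the biomass module.

Every internal reaction is element- and charge-balanced against real
molecular formulas (the tests check all of them, plus a mass-weighted
column-sum identity on the stoichiometric matrix). Multi-step segments
without analytical relevance (lower glycolysis, oxidative PPP, serine
and cysteine synthesis, dNMP synthesis, fatty-acid synthesis, rhamnonate
catabolism) are lumped into single balanced reactions; S-adenosyl
methionine is supplied by a sink because the methionine cycle is outside
the network's scope. GPRs use enzyme-symbol gene ids and deliberately
include the GPR archetypes the screens need: an isozyme pair (HXK1/HXK2),
complexes (PDH, FAS), a multifunctional gene covering five shikimate
steps (ARO1), one gene with two reactions (PTAL, CHS), and an OR of
transporters for resveratrol export.

The generator's options remove defined sub-parts: `include_rhamnose =
FALSE` removes exactly the rhamnose transporter and the
L-rhamnose:NADP+ 1-oxidoreductase (leaving the downstream catabolism),
creating the gap that `gap_fill()` closes from `mini_universal_set()`;
`include_ethanol = FALSE` removes the ethanol route; `knockout` removes
named reactions and errors on unknown ids. The default build takes no
random input and is bit-reproducible; a seed only enters through the
optional bound jitter or the ortholog-table generator
(`generate_ortholog_hits()`, which produces exact pass/fail counts
against the draft thresholds by construction).

What the mini-network emulates is pathway *topology* and balanced
stoichiometry under the study's constraint sets (glucose 2.0 mmol/gDW/h
minimal medium; glucose plus amino acids as a rich-broth stand-in;
glucose 1.0 with growth fixed at 0.055 h$^{-1}$ and trace aromatic
uptake for production analyses; ethanol swept over 0–0.05 mmol/gDW/h).
What it does **not** emulate: the scale (≈100 vs thousands of
reactions), eight-compartment localization, transporter inventories,
isoenzyme redundancy at genome scale, or measured fungal biomass
monomer profiles (the amino-acid, lipid and wall tables are placeholder
single-species stand-ins). Passing tests therefore demonstrate that the
*methods* behave correctly on a faithful miniature — bottleneck
stoichiometry (1 p-coumaroyl-CoA and 3 malonyl-CoA per resveratrol),
monotone responses, exact agreement with independent solvers — not that
any particular genome-scale prediction is numerically reproduced.

## Phenotype validation and scoring

`sole_source_growth_test()` opens one substrate of a role at a time
(default uptake 2.0 mmol/gDW/h, the varied role's other sources closed,
the base medium supplying everything else) and records +/− growth calls;
substrates with no mapped exchange are reported untestable rather than
dropped. `agreement_score()` counts matches and reports percent rounded
half-up to integers (so 11/12 prints as 92%), keeping the raw fraction.
`relative_deviation()` is $100\,|pred-obs|/denominator$ with the
observed (in vivo) rate as the default denominator — the convention
under which the published deviation percentages (12.95%, 1.3%, 0.9%)
are all reproduced from the printed growth rates. The bundled
`growth_phenotype_fixture()` and `growth_rate_fixture()` transcribe the published
validation tables; elicitor- and ethanol-culture yield changes from wet
experiments are documentation-only context and never appear as computed
outputs.

## Problem sizes and runtime

All analyses in the tests and the acceptance script run on the
mini-network: single FBA solves in tens of milliseconds, full FVA in
seconds, the 66-gene deletion screen and the ~70-candidate
overexpression scan in a few seconds each. These sizes keep the entire
validation cycle interactive while exercising every code path the
genome-scale case would use.

## Known limitations

* The simplex refactorizes the basis each iteration; for genome-scale
  models (thousands of reactions) a factorization-updating or external
  LP backend would be the natural extension point.
* SBML support targets Level 3 + fbc version 2 core constructs (species
  with formula/charge, bounds as parameters, GPR association trees,
  flux objectives, gene products); groups, annotations beyond the
  package's own kind/subsystem tags, and SBO terms are not interpreted.
* Balance checking requires integer Hill-notation formulas; polymer or
  R-group pseudo-formulas are treated as unknown and skipped.
* Gap filling is greedy and LP-based: it returns a deterministic minimal
  set under its pruning order, not a globally minimum-cardinality set
  (which would require MILP).
* Thermodynamic (ΔG) consistency, loopless FBA and flux sampling are out
  of scope.
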
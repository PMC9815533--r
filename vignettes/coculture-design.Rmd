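---
title: "Model-driven design of an acetogen-solventogen co-culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven design of an acetogen-solventogen co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncom)
library(tibble)
library(dplyr)
```

## The modeling problem

Acetogens grow on CO₂/H₂ through the Wood–Ljungdahl pathway but conserve
so little energy that their product spectrum is essentially acetate plus
traces of ethanol. Solventogenic clostridia cannot grow on acetate alone —
activating acetate to acetyl-CoA costs an ATP that acetate itself cannot
repay — but when a reduced co-substrate such as lactate supplies redox
power and a second acetyl-CoA stream, acetate is co-assimilated and both
carbons leave as butyrate. A co-culture of the two guilds therefore turns
CO₂/H₂ plus a lactate feed into butyrate, with acetate as the cross-fed
intermediate.

`syncom` implements that design loop as five composable stages, each a
small set of functions over a common model container:

1. **Model handling** (`gem()`, `read_sbml()`, `read_gem_table()`,
   `gem_validate()`, `carbon_balance()`) — a stoichiometric network with
   bounds, gene rules, compartments and an objective.
2. **Curation** (`apply_recipe()`, shipped YAML recipes) — the published
   single-species model edits as inspectable data.
3. **Screening** (`screen_single()`, `screen_pairs()`) — which carbon
   sources, alone and pairwise, support growth.
4. **Community modeling** (`build_community()`, `feasibility_scan()`,
   `max_growth()`, `summarize_scenario()`) — merge, constrain, scan,
   sample.
5. **Fermentation accounting** (`theoretical_acetate()`,
   `fedbatch_stoichiometry()`, `acetate_cofraction()`) — carbon
   bookkeeping for the realized fed-batch.

## Flux balance analysis and its solver

All predictions are steady-state LP problems: maximize (or minimize) one
flux subject to $S v = 0$ and bounds $l \le v \le u$. Unconstrained
reactions use the conventional ±1000 mmol gDW⁻¹ h⁻¹ sentinels.
Stoichiometric equality systems are always rank-deficient (conserved
moieties such as the NAD⁺/NADH or CoA pools duplicate rows) and LP bases
at their vertices are highly degenerate, so the backend reduces the
equality system to a row basis and runs a two-phase bounded-variable
revised simplex with Bland's smallest-index rule, which cannot cycle.
Tolerances: mass balance 1e-7, bounds 1e-8, LP pivoting 1e-9 — several
orders below the 1e-4 h⁻¹ growth-call threshold, so no scientific call
depends on solver noise. Solutions are checked against hand-derived
balances and an independent simplex in the test suite.

## The toy organisms

Full-scale reconstructions are thousands of reactions; every claim the
package makes is instead exercised on two toy models small enough to
balance by hand, shipped as generators.

The **toy solventogen** carries the complete lactate/acetate → butyrate
network: NAD-independent lactate dehydrogenase, pyruvate:ferredoxin
oxidoreductase (PFOR), ferredoxin hydrogenase, acetate kinase + phosphate
acetyltransferase (run toward acetyl-CoA), the thiolase → 3-hydroxybutyryl-CoA
→ crotonyl-CoA → butyryl-CoA chain with the electron-bifurcating
Bcd-EtfAB complex, both butyrate-forming routes (Ptb/Buk, ATP-yielding;
butyryl-CoA:acetate CoA-transferase, ATP-neutral), the Na⁺-translocating
Rnf complex (2 ions per ferredoxin) and the ATP synthase (3 ions per ATP),
an ATP-maintenance sink, and a biomass reaction drawing 1 acetyl-CoA and
2 ATP per unit. Its two reference conversions are derivable on paper:

* lactate only (uptake pinned at 2): LDH makes 2 NADH, the butyrate chain
  needs 3, so Rnf runs once; ferredoxin arithmetic (2 from PFOR + 1 from
  Bcd = 1 Rnf + 2 hydrogenase) leaves **butyrate 1, CO₂ 2, H₂ 2**;
* lactate 1 + acetate 1: ACK/PTA supplies the second acetyl-CoA, Rnf runs
  twice, the hydrogenase is silent: **butyrate 1, CO₂ 1, H₂ 0**.

ATP per lactate rises from 5/6 to 4/3 with acetate co-assimilation — the
energetic reason the growth screen calls lactate + acetate faster than
lactate alone, and the mechanistic core of the design.

The **toy acetogen** lumps the Wood–Ljungdahl pathway into one reaction
(2 CO₂ + 4 H₂ + CoA + ATP → acetyl-CoA + ½ Fd_red), with acetate
production recovering one ATP and the Rnf/ATPase pair converting the
half-ferredoxin into a further third — net **1/3 ATP per acetate**,
deliberately at the low end (autotrophic acetogens are energy-limited, and
values much above ~0.5 would make the toy implausibly comfortable). An
ethanol branch reduces acetyl-CoA with 2 H₂. The fractional ferredoxin
coefficient doubles as a serialization test case.

Neither toy tracks water or protons: with the exchange set fixed to the
fermentation-relevant compounds, any water-producing flux would otherwise
be infeasible, and neither species' energetics depend on them at this
resolution. Carbon counts are tracked per metabolite (CoA-bound carbon on
the acyl moiety only), so `carbon_balance()` certifies every internal
non-biomass reaction at exactly zero with the cofactor ignore list.
Biomass metabolites are cytosolic and drained by non-exchange demand
reactions, keeping the "an exchange touches exactly one extracellular
metabolite" invariant clean.

## Curation as data

The published model curations are shipped as YAML recipes rather than
code, so the same edits can be inspected, diffed and replayed on freshly
downloaded models: reversibility fixes, removal of genome-unsupported
reactions, addition of the Rnf and Nfn complexes, replacement of the
hydrogen ABC-transporter by the ATP synthase, and a stoichiometric
rebalance of the nitrogenase reaction. Where the source curation names a
reaction but not its equation (Rnf, Nfn, ATPase), the recipes carry
standard clostridial biochemistry, with the ion-translocation
stoichiometry (2 ions per ferredoxin, 3 per ATP) flagged in the recipe
notes as an assumption. `apply_recipe()` is pure and transactional: the
first failing edit aborts the whole application, and re-applying a recipe
fails loudly instead of silently no-oping.

## The screening protocol

For each candidate source the exchange bounds are set to
(−20, −0.1) mmol gDW⁻¹ h⁻¹ — uptake *forced* between a minimum and a
maximum, secretion impossible — all other carbon uptakes are closed, ion
and co-substrate exchanges opened to −1000, and biomass synthesis is
maximized. Growth is called strictly above 1e-4 h⁻¹. Because the minimum
uptake is forced, a pair containing an unusable co-substrate (CO₂ for the
solventogen, say) can be *infeasible* rather than merely zero-growth; the
two states are recorded distinctly but render identically (blank) in the
`autoplot()` matrix, since a culture distinguishes neither. The forced
minimum is also why pairwise growth can fail to dominate single-source
growth; with optional uptake (`min_uptake = 0`) dominance is restored and
asserted as a property test.

## Community construction and the environmental-flux frame

`build_community()` keeps each species' cytosol as its own compartment
("cytosol_ca" / "cytosol"), suffixes all species-A intracellular ids with
"_ca", and renames extracellular metabolites through an explicit
two-column namespace map. Mapping is deliberately manual: silent compound
mis-identification is the classic failure mode of community merging, so
unmapped extracellular compounds stay species-private (suffixed) and a
warning lists them. Duplicate exchange reactions for a shared compound
collapse to one, with the union of the bound intervals — the environment,
not either species, owns exchange bounds. Merged reaction count is
audited: $n_A + n_B - (\text{shared exchanges}) + |\text{extras}| + 1$.

A `scenario()` fixes the operating point in environmental units: species
biomass fluxes pinned to $\mu r X$ and $\mu (1-r) X$ (default
$X = 0.22$ gDW l⁻¹, the measured scale of a comparable syngas co-culture),
feed exchanges bounded to (−max, −min) mmol l⁻¹ h⁻¹, and the community
biomass reaction rebuilt with coefficients $(r, 1-r)$ — with biomass
fluxes pinned this choice only scales the reported objective, never
feasibility. `bound_scaling` (default on) multiplies finite, non-sentinel
specific-flux bounds by the owning species' biomass concentration when
converting units; ±1000 sentinels stay untouched as "unbounded". The toys
carry only sentinel bounds, so the switch is inert there; it is exposed
(and documented) because real models carry measured finite bounds whose
treatment under the unit substitution is a genuine modeling choice.

The default scan grid is $r \in \{0.1, \dots, 0.9\}$ step 0.1 and
$\mu \in \{0.005, \dots, 0.1\}$ step 0.005 — the step resolves boundaries
at the 0.005-h⁻¹ scale. The boundary itself needs no grid:
`max_growth()` treats $\mu$ as an LP variable coupled to both biomass
fluxes and maximizes it, and the suite asserts scan/oracle agreement
within one grid step for every ratio, exact halving of $\mu^*$ when the
limiting feed is halved, and cell-wise monotonicity of the feasible set
under feed relaxation. Under the generous reactor-scale default feeds the toy
community is feasible across the whole default grid (its biomass is
stoichiometrically cheap — 1 acetyl-CoA and 2 ATP per unit); the
boundary tests therefore also run under a deliberately H₂-starved feed
that puts $\mu^*$ inside the grid.

## Flux sampling

Within a feasible scenario the flux polytope is characterized by uniform
sampling: an artificially-centered hit-and-run walk whose warm-up points
are the flux-variability vertices, directions are differences between a
random stored point and the running center (degenerate directions are
never proposed), and steps are uniform on the feasible chord. Defaults:
5000 samples, thinning 5, warm-up 100 × (number of non-degenerate
fluxes) capped at 2000; bounds beyond ±1000 are clamped before sampling
so the polytope is bounded; pinned fluxes report sd 0. Every sample — not
just the mean — satisfies $S v = 0$ to 1e-7 and the bounds to 1e-8, which
is what makes the per-species decomposition exact: for each shared
extracellular metabolite, species rates are read off the species-side
stoichiometry and sum to the community exchange flux in every sample. The
sampler's statistical behavior is pinned by a 1-D oracle (a single free
flux on [0, 1] must average 0.5 within 3 standard errors at n = 5000) and
by containment of all means in the flux-variability intervals. Exact
reproduction of any published sampling table is out of scope — the
sampler variant behind those tables is unspecified — so only
deterministic LP quantities are treated as sharp oracles.

## Fed-batch carbon bookkeeping

The experimental-side calculations work on amounts (mmol), not
concentrations, because the lactate feed adds volume. Lactate converted
up to time $t$ is cumulative feed minus measured residual; lactate
oxidation via pyruvate releases one of three carbons as CO₂, so products
can carry at most $2\,\Delta\text{lac}$ lactate carbons; any (iso)butyrate
carbon beyond that must come from co-assimilated acetate
($\text{ac}_{\text{conv}} = (4\Delta\text{but} + 4\Delta\text{iso} -
2\Delta\text{lac})/2$, clipped at zero with a warning under noise); adding
it back to the measured broth acetate gives the theoretical acetate
produced from CO₂. Whether the acetate present at inoculation should be
subtracted is not decidable from the source description, so
`theoretical_acetate()` exposes `subtract_baseline` and defaults to not
subtracting. Isobutyrate is counted like butyrate (C4). Sampling
withdrawals are ignored in the volume series.

`fedbatch_stoichiometry()` normalizes the interval deltas to lactate = −1.
Two estimators ship: the endpoint difference (the rule used on bioreactor
runs) and an origin-constrained least-squares slope pooling all time
points in the interval, which averages measurement noise and is the
estimator used in the acceptance summary.

The synthetic generator `synthetic_fedbatch()` emulates the realized
fed-batch: 2 l reactor, 34 mM acetate at feed start, 3 ml d⁻¹ of 2.5 M
lactate for 19 days sampled daily (20 points), 2% residual lactate,
acetate produced at 1.5× its consumption so it accumulates as observed,
multiplicative Gaussian measurement noise. Its default truth is
lactate −1, acetate −0.4, butyrate +0.7 — inside the measured 0.4–0.5 /
0.6–0.7 regime of the lactate/acetate fermentation and exactly
carbon-closed ($b = (1+a)/2$), which is the condition under which the
carbon-closure bookkeeping can recover the acetate coefficient at all:
with carbon lost to biomass or extra CO₂ the rule systematically
under-reports acetate conversion, a structural property of the method,
not of this implementation. Noise-free recovery is exact; at 5% noise the
pooled estimator's mean absolute relative error over 100 seeds is a few
percent, asserted under 15%.

What the synthetic runs do *not* emulate: biphasic growth with an
adaptation lull, wall growth, sampling-volume loss, isobutyrate formation
(mechanistically unexplained in the source system and deliberately left
at 0 by default), and pH dynamics. Passing the recovery tests therefore
certifies the bookkeeping arithmetic under honest noise, not robustness
to those real-world artifacts.

## Numerical and design choices, in one place

* LP backend written in-package (two-phase bounded simplex, Bland's
  rule) because the installed general-purpose simplex routines fail on
  rank-deficient, degenerate FBA systems; cross-checked against
  `boot::simplex` on a clean full-rank LP and against hand oracles.
* Infinite/oversized bounds: clamped to ±1e6 for optimization, ±1000
  before sampling (the models' own "unbounded" convention).
* Growth-call ties at exactly the threshold are no-growth (strict
  inequality).
* Recipes apply atomically; edits are pure (copy-on-modify).
* Exchange deduplication keys on the mapped extracellular metabolite id;
  bounds take the union interval.
* The toy community's default problem sizes keep the full test suite
  under a minute: 9×20 scans, 400–5000-sample summaries.
* Gene ids are suffixed per species and never deduplicated across
  species; the merged gene count is the sum.

## Limitations

Steady state throughout: no dynamic (kinetic) co-culture simulation, no
time-course concentration predictions — scenario results are rates at an
operating point, not trajectories. Two species only. No gap-filling or
annotation-driven curation. The shipped toys are caricatures tuned for
hand-checkable arithmetic; quantitative correspondence with the
full-scale reconstructions is explicitly not claimed, and reproducing
full-scale results requires downloading those models and replaying the
shipped recipes on them.
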
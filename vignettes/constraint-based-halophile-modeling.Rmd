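---
title: "Constraint-based analysis of halophile metabolic models with halofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of halophile metabolic models with halofba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halofba)
```

## The model and its assumptions

A genome-scale metabolic reconstruction is a curated list of metabolites
and reactions assembled from genome annotation, biochemical databases and
physiological literature. `halofba` represents it as a `metabolic_model`:
metabolites carry a compartment (`c` intracellular, `e` extracellular),
an optional Hill-notation elemental formula and charge; reactions carry a
stoichiometry map, reversibility, flux bounds $\alpha \le v \le \beta$ in
mmol/gDW/h, EC numbers, a boolean gene association, a subsystem label and
a kind (`enzymatic`, `transport`, `exchange`, `biomass`). The
stoichiometric matrix $S$ ($m \times n$) collects the signed
coefficients.

Flux balance analysis makes three assumptions worth keeping in view:

1. **Steady state**: internal metabolite pools neither accumulate nor
   deplete, $S v = 0$. This removes all kinetics from the problem.
2. **Capacity bounds**: each flux is confined to $[\alpha_j, \beta_j]$.
   Exchange-reaction bounds encode the growth medium.
3. **Optimal growth**: among all feasible flux distributions the cell
   realizes one maximizing the biomass reaction, a lumped drain of
   precursors whose flux is the specific growth rate (h$^{-1}$).

Because the system is underdetermined, the optimum is often degenerate.
Flux variability analysis re-solves $2n$ LPs with the objective pinned at
(a fraction of) its optimum, reporting each reaction's attainable
$[v_{\min}, v_{\max}]$; the span relative to $\max(|v_{FBA}|, 10^{-6})$
is the variability percentage. A reported headline flux is trustworthy
when its variability is small; the sweep functions attach this
certificate automatically.

## Sign conventions and media

Every boundary species has one exchange reaction written `x[e] <=>`, so a
negative exchange flux is uptake and a positive one secretion. This is
the convention used by the major constraint-based toolkits, and it keeps
one reaction per species for FVA and yield bookkeeping. All user-facing
interfaces nevertheless take and report uptake as positive rates:
`set_medium(m, c(glc = 3))` fixes glucose uptake at 3 mmol/gDW/h.

`set_medium()` builds a defined minimal medium: named substrates are
pinned at their rate ($\alpha = \beta = -r$, matching the single-rate
simulations the screens reproduce; a `mode = "max"` variant bounds uptake
from above instead, and is what the substrate screen uses so that unusable
substrates are simply not consumed rather than forcing infeasibility).
Every other organic-carbon uptake is closed — a species counts as organic
carbon when its formula contains C and it is not CO2, with an id
whitelist covering formula-less inorganics — while water, O2 (unless
anaerobic), CO2, ammonia, nitrate/nitrite, phosphate, sulfate and sodium
chloride remain open. Secretion is never closed, so by-products such as
lactate or surplus betaine can always leave.

One deliberate exception: the alanine-supplementation scenario applies
its NaCl rate as an uptake *cap* rather than a two-sided pin. Salt has no
catabolic fate, so forcing a fixed net salt uptake beyond the biomass
salt demand would render any mass-balanced model infeasible; capping
availability preserves the intent (salt-limited medium) without the
artifact.

## The LP solver

No linear-programming backend is assumed: the package implements the LP
it needs. `solve_lp()` is a dense two-phase bounded-variable primal
simplex with Bland's anti-cycling rule; nonbasic variables rest at a
finite bound and iterations may end in bound flips. The basis system is
re-factorized every iteration via LU — at the tens-of-variables scale of the
shipped fixtures robustness matters more than speed, and genome-scale
models (thousands of reactions) remain tractable in seconds per solve.
Tolerances: feasibility and optimality $10^{-9}$; a solution is accepted
only with steady-state residual below $10^{-8}$ (the suite observes
$<10^{-14}$). Infeasible and unbounded problems are reported as distinct
statuses, never as zero growth. Variables with both bounds infinite are
rejected (every reaction in practice has at least one finite default
bound: irreversible 0…1000, reversible −1000…1000 mmol/gDW/h).

Correctness is established by dual routes in the test suite: exhaustive
enumeration of basic solutions on hundreds of random toy models (exact
agreement to $10^{-6}$), and an independent scipy/HiGHS cross-check of
the fixture optimum.

## Quality control of reconstructions

*Dead ends.* A metabolite is a dead end when it has no producing or no
consuming reaction, counting a reversible reaction as both and counting
exchange and biomass reactions as legitimate partners (exchanges exist
precisely to resolve boundary gaps). Dead ends localize reconstruction
gaps; proposing the filling reaction is intentionally left to the
curator.

*Mass and charge balance.* Each non-boundary reaction's per-element
deficit (products minus substrates) is computed from metabolite formulas;
balanced means all deficits and the charge deficit are zero (tolerance
$10^{-9}$). Reactions with any formula-less participant get the verdict
`unknown` rather than a false positive or negative; exchanges are
`boundary` by construction. The classic failure mode — a missing proton
in a kinase reaction — appears as an exact $\{H: -1\}$ deficit with
charge deficit −1, and vanishes when `h[c]` is added.

*Comparison across models.* Reaction ids are not comparable across
publications, so `compare_models()` matches by canonical signature:
(species, coefficient) pairs keyed by elemental formula where available,
compartment-normalized, direction-normalized, sorted. Reactions whose
signature cancels to nothing under this keying (pure same-species
transport) are excluded — their signature carries no chemistry to match
on — and a curated mapping can override the keying where formulas are
missing or ambiguous.

## The synthetic-network module

The package generates all of its own test inputs:

* `make_toy_chain()` / `make_branched_toy()` — analytic models whose FBA
  optima are known in closed form (`uptake_bound`;
  `min(sum(capacities), sink_bound)`), the latter with deliberately
  degenerate optima to exercise FVA.
* `make_random_network()` — a mass-balanced core (a cycle over the
  metabolites plus random chords; integer coefficients in {1, 2} and
  single-element formulas keep brute-force oracles exact) into which a
  requested number of dead ends and elemental imbalances is injected,
  with the ground truth recorded. Identical seed, identical output; the
  caller's RNG stream is left untouched.
* `make_mini_halophile()` — a deterministic 50-reaction model carrying
  everything the osmoadaptation studies need: glucose / choline /
  alanine / nitrate / O2 / ammonia / NaCl exchanges, a lumped but
  elementally balanced glycolysis–TCA–respiration energy module with
  lactate fermentation and respiratory nitrate reduction, aspartate and
  glutamate nodes, the four-step ectoine branch (EC 2.7.2.4, 1.2.1.11,
  2.6.1.76 and 2.6.1.46, 2.3.1.178, 4.2.1.108), the two-step
  choline→betaine pathway with both step-one enzymes (EC 1.1.99.1,
  1.14.15.7, then 1.2.1.8), and a biomass reaction with an
  osmoprotectant requirement satisfiable by either betaine or ectoine.

Design choices inside the fixture worth knowing: redox is carried by an
NAD/NADH pair written as an H$_2$ carrier so that every redox reaction
balances without free protons; the osmoprotectant requirement is a
formula-free pseudo-species `osm[c]` produced from either betaine or
ectoine, which is what couples osmolyte synthesis to growth and makes
choline supplementation growth-stimulating (betaine costs no biosynthetic
carbon and its oxidation yields NADH); coefficients are chosen for
elemental balance and convenient rational optima, not biological
accuracy. Its declared substrate phenotypes (`mini_halophile_phenotypes()`)
follow from construction: glucose and alanine support growth, choline and
betaine satisfy only the osmolyte demand, lactate's transporter is
export-only, sorbitol has no route at all.

What the fixture does **not** emulate: genome-scale combinatorial
redundancy (hundreds of alternate routes), realistic P/O ratios and
maintenance ATP, salinity-dependent biomass composition, or regulatory
effects such as betaine inhibition of choline oxidation (a kinetic
observation outside FBA's scope). Passing tests on the fixture therefore
certify the *analysis machinery* — LP correctness, audit exactness,
sweep logic — not the biology of any particular reconstruction.

## Case-study semantics

"Betaine production" and "ectoine production" are read as the flux
through the pathway's terminal synthesis step (EC 1.2.1.8 and EC
4.2.1.108 respectively). At a biomass optimum nothing is gratuitously
excreted, so the excretion flux alone would under-report production in
any growth-coupled model; the excretion rate is reported alongside, and
the stoichiometric ceiling obtained by maximizing the synthesis step
directly (`max_yield`) bounds the growth-coupled yield from above. In the
ectoine sweep, absence of exogenous osmoprotectants is simulated by
closing choline and betaine uptake and knocking out the two step-one
choline-oxidation reactions. Percent stimulations in the alanine scenario
are computed on fluxes rounded to 4 decimals, the precision growth rates
are conventionally reported at.

Screen thresholds: growth counts as positive above $10^{-6}$ h$^{-1}$;
a reaction counts as flux-carrying above $10^{-9}$ mmol/gDW/h; an
activity test is positive above $10^{-6}$. These are numerical-noise
floors, far below any biologically meaningful rate, and verdicts are
insensitive to the uptake rate across the conventional 3–10 mmol/gDW/h
screening range (the suite checks this invariance).

## Numerical and design notes

* Coefficient equality uses a $10^{-9}$ tolerance; rational coefficients
  (e.g. 1/3) survive JSON round trips at full double precision.
* Table loading collects *all* errors (missing columns, malformed
  equations, duplicate ids, dangling references) before failing, naming
  the offending rows; loading is row-order-insensitive up to index
  permutation, with identical FBA optima.
* Gene associations are boolean expressions over locus tags; bare
  comma/semicolon lists are treated as OR (isoenzymes).
* FVA pins the objective with a relative slack of $10^{-7}$ to absorb LP
  round-off; the sandwich $v_{\min} \le v_{FBA} \le v_{\max}$ and
  objective preservation at both extremes are asserted on every fixture.
* Problem sizes used by the shipped verification: 200 random toy models
  of ≤ 8 reactions for oracle equivalence (kept small so exhaustive
  vertex enumeration stays exact), ~50 random QC networks totalling
  ≥ 1000 reactions for audit sensitivity/specificity, and the 50-reaction
  fixture for the case studies — sizes at which every oracle is
  brute-force exact while the full battery completes in well under a
  minute.

## Worked session

```{r example}
m <- make_mini_halophile()
audit_model(m)

sol <- solve_fba(m, constraints = set_medium(m, c(glc = 3)))
sol

choline_betaine_sweep(m, glucose_rate = 3, choline_rates = c(0, 1, 2))

ectoine_production_sweep(m, glucose_rates = c(3, 6, 10), fva = FALSE)

alanine_scenario(m)$stimulation_percent
```

## Limitations

The package analyzes models; it does not build them. Database mining,
genome annotation, biomass-composition derivation and gap *filling* are
out of scope, as are SBML I/O, thermodynamic directionality assignment,
parsimonious/dynamic FBA, knockout-essentiality scans and any kinetic or
regulatory modelling. Reproducing a published reconstruction's absolute
numbers requires that reconstruction's own reaction list; the packaged
in-vivo phenotype reference (`table2_reference()`) makes the concordance
computation available offline the moment such a file is supplied.
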
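# halofba

Constraint-based analysis of genome-scale metabolic reconstructions of
halophilic bacteria — the class of models used to study how organisms such
as *Chromohalobacter salexigens* grow across extreme salinities by
synthesizing or importing compatible solutes (ectoine, glycine betaine,
choline). The package is aimed at curators of such reconstructions and at
modelers running growth and osmolyte-production simulations on them.

## What it does

A metabolic reconstruction is represented by its stoichiometric matrix
**S** (m metabolites × n reactions), where `S[i, j]` is the signed
coefficient of metabolite *i* in reaction *j*. The core computation is
**flux balance analysis** (FBA): the linear program

```
max  v_biomass
s.t. S v = 0            (steady state)
     α_j ≤ v_j ≤ β_j    (flux bounds, mmol/gDW/h)
```

whose optimum is the specific growth rate (h⁻¹). **Flux variability
analysis** (FVA) then fixes the objective at its optimum and
minimizes/maximizes each flux in turn, quantifying alternate-optima
spread. Both run on a bounded-variable primal simplex implemented in the
package (two phases, Bland's anti-cycling rule), verified in the test
suite against an exhaustive vertex-enumeration oracle and an external
HiGHS cross-check.

Around that core the package provides:

* **Model representation and I/O** — an in-memory `metabolic_model`
  (metabolites with formulas/charges, reactions with stoichiometry,
  bounds, EC numbers, gene associations), a documented TSV dialect with a
  human-readable reaction-equation grammar (`"2 A[c] + B[c] -> C[c]"`),
  a versioned JSON schema with lossless round trips, and a converter for
  supplementary spreadsheet workbooks.
* **Reconstruction quality control** — dead-end metabolite detection,
  per-element mass and charge balancing from Hill-notation formulas,
  metabolite/reaction adjacency matrices, network statistics (counts by
  kind and compartment, subsystem distribution, monofunctional enzyme
  fraction), and cross-model reaction comparison by canonical chemical
  signature.
* **Phenotype screens** — substrate-utilization verdicts (sole carbon,
  and sole nitrogen for nitrogenous substrates), enzyme-activity
  feasibility tests, growth-vs-uptake curves, and concordance against a
  packaged in-vivo reference table.
* **Osmoadaptation case studies** — the choline→betaine supplementation
  sweep, the de-novo ectoine production sweep with yields and
  stoichiometric ceilings, the alanine supplementation scenario, and
  EC-number pathway audits.
* **Synthetic networks** — analytic toy models with known LP optima,
  random QC networks with recorded injected defects, and a curated,
  elementally balanced mini-halophile fixture carrying the full ectoine
  and choline-betaine pathways, so everything above runs offline.

## Worked example

```r
library(halofba)

m <- make_mini_halophile()
m
#> <metabolic_model> 45 metabolites, 50 reactions, 23 genes
#>   reactions by kind: enzymatic=23, transport=13, exchange=13, biomass=1
#>   objective: BIOMASS

audit_model(m)
#> <audit_report>
#>   dead-end metabolites: 0
#>   unbalanced reactions: 0
#>   reactions with unknown formulas: 3
```

The audit confirms the fixture has no reconstruction gaps (every species
has a producer and a consumer) and that every formula-covered reaction is
elementally balanced; the three "unknown" reactions involve the
formula-free osmoprotectant pseudo-species by design.

```r
sol <- solve_fba(m, constraints = set_medium(m, c(glc = 3)))
sol
#> <flux_solution> status: optimal
#>   objective (BIOMASS): 0.6500
```

With glucose fixed at 3 mmol/gDW/h as sole carbon source the fixture
grows at 0.65 h⁻¹. Supplementing choline stimulates growth — the
bacterium satisfies its osmoprotectant requirement via the cheaper
two-step choline→betaine oxidation instead of de-novo ectoine synthesis,
and gains reducing power on top:

```r
choline_betaine_sweep(m, glucose_rate = 3, choline_rates = c(0, 1, 2))
#>   choline_uptake growth_rate betaine_flux betaine_secretion  ...variability...
#> 1              0      0.6500            0            0.0000          0
#> 2              1      0.8723            1            0.1277          0
#> 3              2      0.9149            2            1.0851          0
```

Growth rises monotonically with choline, betaine production tracks the
choline supply, surplus betaine is excreted, and the attached FVA
certifies the fluxes are unique (variability 0%). The alanine scenario
compares growth and ectoine production with and without alanine in a
glucose/NaCl medium:

```r
alanine_scenario(m)$stimulation_percent
#>   growth  ectoine
#> 55.37610 55.37610
```

## Scope notes

Reproducing a published reconstruction's absolute growth and flux values
requires that model's full reaction list (distributed as supplementary
material of the original publication, not bundled here); given such a
file converted to the TSV dialect, `read_model_tables()` loads it and
every analysis above applies unchanged. The package deliberately leaves
out automated gap-filling, thermodynamic directionality assignment,
parsimonious/dynamic FBA variants, and kinetic or regulatory modelling.
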
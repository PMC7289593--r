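# syntherm

Thermodynamic analysis of anaerobic microbial redox processes, for
geomicrobiologists and biogeochemists who need to ask: *is this
metabolism feasible here, and who can partner with whom?*

In anoxic sediments and aquifers, hydrogen partial pressure is the
master variable of anaerobic carbon turnover. H2-consuming respirations
(sulfate reduction, methanogenesis, nitrate reduction, organohalide
respiration, ...) each have a lowest H2 level at which they still yield
the minimum energy an anaerobe can conserve (about −10 ± 1 kJ/mol);
H2-*producing* half-processes such as the anaerobic oxidation of methane
(AOM) have the opposite problem — they are endergonic unless a partner
keeps H2 low. `syntherm` computes all sides of this bookkeeping:

* **ΔG′ evaluation**: ΔG′ = ΔG°′ + RT ln Q from signed stoichiometries
  and environmental activities, at the pH-7 standard state (protons
  enter Q as a_H+/10⁻⁷), with results on per-reaction, per-reference,
  per-acceptor and per-electron bases.
* **Redox potentials**: E°′ = −ΔG°′/(nF), F = 96.5 kJ/V.
* **H2 thresholds and ceilings** in closed form, in atm and (via
  Henry's law) molar units, and their intersection into a
  **syntrophy feasibility window**.
* **Energy ladders** ranking competing electron-accepting processes,
  and ΔG′-versus-[H2] profile curves.
* A packaged, validated **reference scenario** (AOM coupled to sulfate
  reduction and to reductive dechlorination by *Dehalococcoidia*-type
  organohalide respirers) and a seeded **synthetic-scenario generator**
  for property-based testing.

## Worked example

How much energy does methane oxidation coupled to tetrachloroethene
(PCE) dechlorination yield under environmentally relevant
concentrations, and can the partnership work via hydrogen transfer?

```r
library(syntherm)
bundle <- scenario_bundle()
env <- bundle$conditions$env_coupled

delta_g_prime(bundle$reactions$coupled$coupled_pce, env, basis = "per_reference")
#> <energy_result> dG' = -574.021 kJ (per_reference), T = 298.15 K
#>          basis dg_prime_kj dg0_prime_kj
#>   per_reaction  -574.02124    -557.9000
#>  per_reference  -574.02124    -557.9000
#>   per_acceptor  -143.50531    -139.4750
#>   per_electron   -71.75265     -69.7375
#> E0' = 0.723 V
```

Per mole of CH4 the coupled reaction yields −574.0 kJ under *in situ*
activities (−557.9 kJ at standard state): vastly more than the −5.0
kJ/mol CH4 of the classical AOM–sulfate partnership under the same
conditions. Is the H2 relay feasible?

```r
syntrophy_window(bundle$reactions$h2$pce_to_tce, bundle$conditions$env_profiles)
#> <syntrophy_window> floor 7.484e-34 M, ceiling 6.64e-11 M: FEASIBLE
```

The dechlorinator can draw H2 down to ~10⁻³⁴ M before hitting its −10
kJ/mol H2 floor, while AOM tolerates H2 up to ~7 × 10⁻¹¹ M under these
conditions — a wide open window, which is why organohalide respirers
are, thermodynamically, ideal AOM partners. Where do the competing H2
sinks sit on the energy ladder at standard state?

```r
energy_ladder(bundle$reactions$h2[-1], bundle$conditions$standard)
#>   rank                id    dg_kj
#> 1    1        pce_to_tce -86.6500
#> 2    2 nitrate_reduction -79.0500
#> 3    3    iron_reduction -22.3000
#> 4    4 sulfate_reduction -18.9875
#> 5    5    methanogenesis -16.9250
#> 6    6      acetogenesis -13.0250
```

kJ per mole of electrons: PCE dechlorination out-competes every other
H2 sink, with nitrate reduction close behind.

`reference_tables()` recomputes the full reference tables (standard
free energies on all bases, redox potentials, the coupled-reaction
table with its documented-discrepancy flags, and the ΔG′-vs-H2 curve
data). A thin command-line wrapper is included at
`inst/cli/syntherm.R` (`dgprime`, `threshold`, `ceiling`, `window`,
`ladder`, `curve`, `reproduce`, `synth-*` subcommands; see
`?run_cli`). The methods vignette
(`vignettes/anaerobic-energetics.Rmd`) documents the conventions,
ambiguous-source decisions, and known discrepancies.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the packaged reaction definitions and environmental
activity set alone, the environmental free-energy changes (kJ per mol
CH4) of AOM coupled to sulfate reduction and to the five reductive
dechlorination / dihaloelimination partners, and writes them as JSON.
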
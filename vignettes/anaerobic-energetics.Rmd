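---
title: "Free-energy analysis of H2- and CH4-based anaerobic redox processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy analysis of H2- and CH4-based anaerobic redox processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntherm)
```

## The model

In anoxic environments the feasibility of a microbial redox process is set
by its Gibbs free-energy change under *in situ* conditions. For a reaction
with signed stoichiometric coefficients $\nu_i$ (reactants negative),

$$\Delta G' = \Delta G^{\circ\prime} + RT \ln Q, \qquad
  Q = \prod_i a_i^{\nu_i},$$

where $\Delta G^{\circ\prime}$ is the standard free-energy change at pH 7
(solutes at 1 M, gases at 1 atm, 298.15 K), $R = 8.314\ \mathrm{J\,K^{-1}\,mol^{-1}}$,
and $a_i$ are activities, taken throughout to approximate concentrations
(no ionic-strength or speciation corrections). Three conventions matter
and are fixed package-wide:

* **pH-7 standard state.** Because tabulated $\Delta G^{\circ\prime}$
  values already absorb the proton term at pH 7, the proton enters $Q$ as
  $(a_{H^+}/10^{-7})^{\nu}$: at pH 7 protons drop out of $Q$ entirely,
  and the proton coefficient of a reaction is immaterial. This is the
  only convention under which the environmental free energies of the
  packaged CH4-coupled reactions reproduce their reported values.
* **Water and solids** have activity exactly 1.
* **Mixed-phase activities are caller-supplied.** CH4 is a gas and its
  standard state is 1 atm, but the environmental condition sets report a
  molar CH4 concentration; the engine substitutes whatever activity value
  the condition set supplies, without phase coercion, because that is
  what reproduces the reported environmental free energies. Henry's law
  is applied only where explicitly requested.

The standard redox potential follows from
$\Delta G^{\circ\prime} = -nF\,\Delta E^{\circ\prime}$ with
$F = 96.5\ \mathrm{kJ\,V^{-1}}$ and $n$ the moles of electrons
transferred (2 per H2 consumed; 8 per CH4 oxidised to bicarbonate).

## Thresholds, ceilings and the syntrophy window

Anaerobes can only conserve energy when a reaction yields more than a
minimum quantum, conventionally $-10 \pm 1$ kJ/mol. For an H2-consuming
reaction $a\,EA + b\,\mathrm{H_2} \rightarrow c\,C + d\,D$ this implies a
*lowest usable H2 level* — the consumption threshold — obtained in closed
form by solving $\Delta G' = \Delta G_{\min}$ for the H2 activity:

$$a_{\mathrm{H_2}} = \left(\frac{(a_C)^c (a_D)^d}{(a_{EA})^a}
  \exp\!\left(\frac{\Delta G_{\min} - \Delta G^{\circ\prime}}{RT}\right)
  \right)^{1/b}.$$

Anaerobic oxidation of methane (AOM),
$\mathrm{CH_4} + 3\mathrm{H_2O} \rightarrow \mathrm{HCO_3^-} +
4\mathrm{H_2} + \mathrm{H^+}$ with
$\Delta G^{\circ\prime} = +135.4$ kJ/mol CH4, is endergonic on its own;
the same algebra applied to the H2 *product* yields a **ceiling**: the
highest H2 level at which AOM still clears $\Delta G_{\min}$. A
hydrogen-transferring syntrophy is feasible exactly when the partner's
floor lies at or below the producer's ceiling
(`syntrophy_window()`). Organohalide respiration (e.g. PCE
dechlorination, $-173.3$ kJ/mol H2) holds H2 many orders of magnitude
below the AOM ceiling, which is why reductive dechlorinators are, on
thermodynamic grounds, better AOM partners than sulfate reducers.

`delta_g_prime()` reports every normalisation basis (per reaction
occurrence, per mole of reference species, per mole of acceptor, per
mole of electrons); threshold operations require the basis of
$\Delta G_{\min}$ to be stated explicitly (`per_mol_h2` is the
documented default for consumers, per mol CH4 for the AOM ceiling),
because reported thresholds in the literature mix these bases.

Gas/aqueous interconversion uses Henry constants in
mol m$^{-3}$ Pa$^{-1}$ ($7.8\times10^{-6}$ for H2,
$1.4\times10^{-5}$ for CH4), i.e.
$M = \mathrm{atm} \times 101325 \times K_H / 1000$; the H2 constant
reproduces the known solubility of about $7.9\times10^{-4}$ M at 1 atm.

## The packaged scenario

`scenario_bundle()` loads CSV fixtures shipped with the package:

* seven H2-based reactions (AOM, acetogenesis, methanogenesis, sulfate
  reduction, ferric iron reduction, nitrate reduction to nitrite, PCE
  dechlorination) with $\Delta G^{\circ\prime}$ stored per mole of
  electron acceptor;
* per-H2 reductive-dehalogenation half-reactions;
* eight CH4-coupled reactions;
* condition sets: `standard`, the environmental activity set used for
  the coupled reactions (`env_coupled`), its subset used for
  $\Delta G'$-vs-H2 curves (`env_profiles`), and the high-methane
  `aom_breakpoint` set (2.14 atm CH4, 20.2 mM HCO3-).

`reference_tables()` then recomputes — never transcribes — the derived
tables.

```{r}
reference_tables("h2_redox_e0")
reference_tables("aom_coupled_dg")[, c("id", "dg0_per_ch4",
                                       "dg_prime_per_ch4", "flag")]
```

### Choices where the sources are ambiguous or inconsistent

* **Which $\Delta G^{\circ\prime}$ column is authoritative.** The source
  compilation reports the same reactions per mol H2, per mol acceptor
  and per mol electrons, and the columns disagree by up to 0.2 kJ from
  independent rounding (acetogenesis: $-26.1 \times 4 = -104.4$ vs
  $-52.1 \times 2 = -104.2$ per reaction). The package stores the
  per-acceptor column: it is the only basis from which the reported
  redox-potential column is recovered at 0.01 V for all seven reactions
  (from the per-H2 column, acetogenesis would give 0.135 V, printing as
  0.14 rather than the reported 0.13).
* **Per-H2 dehalogenation half-reactions.** Only the PCE step is
  reported per H2 ($-173.3$); the TCE, 2-CP, MCB and DCA steps are
  back-calculated from the coupled reactions and the AOM value, to
  0.1 kJ. The PCE step cross-checks: $(-557.9 - 135.4)/4 = -173.325$.
* **Dihaloelimination water count.** The coupled DCA reaction is
  transcribed as reported with 2 H2O although elemental balance
  requires 3; charge still balances, water activity is 1, and coupling
  AOM with 4 half-steps rebuilds the balanced form — so free energies
  are unaffected and only the water coefficient differs.
* **The nitrate row.** Under the stated environmental activities the
  nitrate-coupled reaction computes to $-522.0$ kJ/mol CH4, not the
  reported $-501.4$; no convention we tried recovers the reported
  number, so `reference_tables()` flags the row
  `documented-discrepancy` and reports the computed value. The ferric
  iron row, sometimes also suspected, does reproduce ($-144.18$
  against a reported $-144.1$).
* **Internal inconsistency of the coupled standard values.** Coupling
  AOM with 4 x the per-H2 nitrate (or iron) reaction gives $-497.0$
  (or $-43.0$) kJ/mol CH4, versus reported coupled values of $-510.7$
  (and $+46.2$): the transcribed compilation's two tables are mutually inconsistent for
  these acceptors (plausibly different mineral phases/data sources).
  The coupling identity is therefore asserted only for the six
  consistent rows.
* **Reported threshold concentrations.** The theoretical H2 threshold
  column of the literature compilation (e.g. 15.4 nM for sulfate reduction, 162.3 nM
  for methanogenesis) is *not* recovered from the closed form under its
  stated convention (standard activities, $-10$ kJ/mol H2): we obtain
  9.9 nM and 52.4 nM. Curiously, the iron, nitrate and PCE entries are
  recovered almost exactly when evaluated under the *environmental*
  activity set and read in molar units, suggesting a provenance mix-up
  in that compilation; this is noted, not asserted. Likewise the well-known
  29.7 uM (3,888 Pa) AOM breaking point is not recovered from the
  stated inputs (we obtain $1.37\times10^{-6}$ atm $= 1.09$ nM); the
  cited provenance may use different conventions. Neither quantity is a
  reproduction target; the threshold machinery is instead validated by
  a 1000-case property suite (closed form vs an independent bisection
  on the $\Delta G'$ evaluator, to $10^{-9}$ relative error).

## Numerical choices

* $R = 8.314\times10^{-3}$ kJ/K/mol and $T$ defaults to 298.15 K (the
  sources mix 298 and 298.15 K; the difference is below 0.01% of RT).
* Stoichiometric coefficients are exact rationals
  (numerator/denominator pairs); scaling and coupling with rational
  weights are drift-free, and a species is dropped from a combination
  only when its coefficient is exactly zero. Non-rational coupling
  weights fall back to floating point with a $10^{-12}$ cancellation
  threshold.
* $\Delta G'$ is evaluated on the log scale, so quotients that would
  overflow `exp()` are handled; `reaction_quotient()` itself may return
  `Inf` for pathological activity sets.
* Free energies are conventionally rounded to 0.1 kJ, potentials to
  0.01 V, thresholds to 3 significant figures when compared against
  reported values; the package returns full precision.
* An empty reaction (complete cancellation) is representable: its
  energies are zero and it is excluded from ladders.
* Ladder ties are broken lexicographically by reaction id.

## The synthetic generator

`random_consumer_reaction()` draws reactions of the canonical consumer
shape $a\,EA + b\,\mathrm{H_2} \rightarrow c\,C + d\,D$ with $b \in
1..4$, coefficients up to 4, and $\Delta G^{\circ\prime}$ uniform over
$[-193, -26]$ kJ/mol H2 — the span from acetogenesis to reductive
dechlorination. Activities are log-uniform over $[10^{-9}, 1]$,
nanomolar trace compounds up to standard state. All generated species
are charge-neutral, so charge balance holds by construction; the
generator makes no attempt at elemental self-consistency of
$\Delta G^{\circ\prime}$ (out of scope). Draw order is fixed and a seed
fully determines the output, so property suites are reproducible. What
a green property suite establishes is the internal consistency of the
threshold algebra, the normalisations, reversal antisymmetry and
coupling additivity — not agreement with any measured chemistry, which
is covered separately by the packaged scenario.

## Limitations

* No kinetics: thresholds are thermodynamic floors, not rate
  predictions.
* No activity-coefficient, ionic-strength, speciation or temperature
  corrections of $\Delta G^{\circ\prime}$ (enthalpies are not part of
  the inputs).
* $\Delta G^{\circ\prime}$ values are inputs, not derived from
  formation energies.
* The documented source discrepancies above are reported, flagged and
  excluded from reproduction checks rather than reverse-engineered.
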
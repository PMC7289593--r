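Package: syntherm
Title: Thermodynamics of Syntrophic Anaerobic Redox Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gibbs free-energy analysis of hydrogen- and methane-based
    anaerobic redox reactions under environmental conditions. Evaluates
    delta-G-prime at the pH-7 standard state from signed stoichiometries
    and activity sets, converts free energies to redox potentials,
    computes closed-form hydrogen consumption thresholds and the hydrogen
    ceiling above which anaerobic oxidation of methane (AOM) becomes
    unfavourable, intersects the two into syntrophy feasibility windows,
    and ranks competing electron-accepting processes on an energy ladder.
    Ships transcribed literature scenarios (AOM coupled to sulfate
    reduction and to organohalide respiration) and a seeded generator of
    random charge-balanced reactions for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
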
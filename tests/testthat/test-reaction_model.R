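test_that("validate_reaction checks charge balance and electron counts", {
  registry <- read_species_registry(
    system.file("extdata", "species.csv", package = "syntherm"))
  sr <- sulfate_reduction_rxn()
  expect_length(validate_reaction(sr, registry), 0)

  # forced charge imbalance: one proton instead of two
  bad <- reaction("bad_sr",
                  "SO4-2(aq) + 4 H2(g) + H+(aq) -> H2S(aq) + 4 H2O(w)",
                  dg0_prime = -151.9, reference_species = "SO4-2",
                  electron_donor = "H2", electron_acceptor = "SO4-2")
  v <- validate_reaction(bad, registry)
  expect_length(v, 1)
  expect_match(v, "charge imbalance")

  # declared electron count contradicting the 2 e-/H2 donor rule
  wrong_n <- reaction("wrong_n",
                      "SO4-2(aq) + 4 H2(g) + 2 H+(aq) -> H2S(aq) + 4 H2O(w)",
                      dg0_prime = -151.9, reference_species = "SO4-2",
                      electron_donor = "H2", electron_acceptor = "SO4-2",
                      n_electrons = 6)
  v <- validate_reaction(wrong_n, registry)
  expect_length(v, 1)
  expect_match(v, "expected 8")

  # unknown species is an error, not a violation
  orphan <- reaction("orphan", "X(aq) + H2(g) -> Y(aq)", dg0_prime = -50,
                     electron_donor = "H2")
  expect_error(validate_reaction(orphan, registry), "X")
})

test_that("every packaged reaction passes validation", {
  bundle <- scenario_bundle()
  for (set in bundle$reactions) {
    for (r in set) {
      expect_length(validate_reaction(r, bundle$registry), 0)
    }
  }
})

test_that("scale_reaction is exact and preserves the per-reference energy", {
  sr <- sulfate_reduction_rxn()
  quarter <- scale_reaction(sr, "1/4")
  expect_equal(dg0_reaction(quarter), -151.9 / 4) # per-H2 form, -37.975
  expect_equal(quarter$dg0_prime, sr$dg0_prime)   # per mol SO4-2 unchanged
  expect_equal(coef(quarter)[["H2"]], -1)
  expect_equal(quarter$n_electrons, 2)

  expect_equal(coef(scale_reaction(sr, 1)), coef(sr))
  # exact inverse: no floating-point drift through 2 then 1/2
  back <- scale_reaction(scale_reaction(sr, 2), "1/2")
  expect_identical(back$num, sr$num)
  expect_identical(back$den, sr$den)

  expect_error(scale_reaction(sr, 0), "factor")
  expect_error(scale_reaction(sr, -2), "factor")
})

test_that("coupling AOM to dechlorination cancels H2 and sums energies", {
  bundle <- scenario_bundle()
  aom <- bundle$reactions$h2$aom
  pce <- bundle$reactions$half_h2$pce_to_tce
  coupled <- couple_reactions(aom, 1, pce, 4, id = "aom_pce")

  nu <- coef(coupled)
  expect_false("H2" %in% names(nu))
  expect_equal(nu[["CH4"]], -1)
  expect_equal(nu[["PCE"]], -4)
  expect_equal(nu[["TCE"]], 4)
  expect_equal(nu[["H+"]], 5)
  expect_equal(nu[["Cl-"]], 4)
  expect_equal(nu[["H2O"]], -3)
  expect_equal(nu[["HCO3-"]], 1)
  # 135.4 + 4 * (-173.3) = -557.8, within 0.2 kJ of the tabulated -557.9
  expect_equal(dg0_reaction(coupled), -557.8, tolerance = 1e-12)
  expect_equal(coupled$n_electrons, 8) # recomputed from the CH4 donor rule
  expect_equal(coupled$electron_acceptor, "PCE")

  # AOM + its exact reverse (hydrogenotrophic methanogenesis) cancels fully
  mg <- bundle$reactions$h2$methanogenesis
  empty <- couple_reactions(aom, 1, mg, 1)
  expect_length(empty$species, 0)
  expect_equal(dg0_reaction(empty), 0)

  # AOM + 4 x per-H2 sulfate reduction reproduces the coupled reaction
  sr4 <- scale_reaction(bundle$reactions$h2$sulfate_reduction, "1/4")
  cs <- couple_reactions(aom, 1, sr4, 4, id = "aom_sulfate")
  expect_equal(dg0_reaction(cs), 135.4 - 151.9)
  expect_setequal(names(coef(cs)),
                  c("CH4", "SO4-2", "H+", "HCO3-", "H2S", "H2O"))

  expect_error(couple_reactions(aom, 0, mg, 0), "zero")
})

test_that("reaction quotient follows activities, pH convention, exponent laws", {
  r <- reaction("cs",
                "CH4(g) + SO4-2(aq) + H+(aq) -> HCO3-(aq) + H2S(aq) + H2O(w)",
                dg0_prime = -16.5, reference_species = "CH4",
                electron_donor = "CH4", electron_acceptor = "SO4-2")
  env <- condition_set(c(`HCO3-` = 2.02e-2, H2S = 8e-4,
                         CH4 = 3e-5, `SO4-2` = 5.2e-3))
  # hand product: (0.0202 * 8.0e-4) / (3.0e-5 * 5.2e-3)
  expect_equal(reaction_quotient(r, env), (2.02e-2 * 8e-4) / (3e-5 * 5.2e-3))

  std <- standard_conditions_for(r)
  expect_equal(reaction_quotient(r, std), 1)

  # Q(scale(r, 2)) = Q(r)^2
  expect_equal(reaction_quotient(scale_reaction(r, 2), env),
               reaction_quotient(r, env)^2)

  # at pH 7 the proton coefficient is irrelevant; away from 7 it is not
  r5 <- reaction("cs5",
                 "CH4(g) + SO4-2(aq) + 5 H+(aq) -> HCO3-(aq) + H2S(aq) + H2O(w)",
                 dg0_prime = -16.5, reference_species = "CH4")
  expect_equal(reaction_quotient(r5, env), reaction_quotient(r, env))
  env6 <- condition_set(env$activities, pH = 6)
  expect_false(isTRUE(all.equal(reaction_quotient(r5, env6),
                                reaction_quotient(r, env6))))
  # one extra consumed proton at pH 6 multiplies Q by 10^-1... the
  # quotient convention: a_H+/1e-7 = 10 at pH 6, reactant => divide by 10
  expect_equal(reaction_quotient(r5, env6) * 10^4, reaction_quotient(r, env6))

  # missing activity errors with the species name
  expect_error(reaction_quotient(r, condition_set(c(CH4 = 1))), "SO4-2")
})

test_that("quotients of coupled reactions multiply", {
  a <- reaction("a", "A(aq) + 2 H2(g) -> B(aq)", dg0_prime = -30,
                reference_species = "H2", electron_donor = "H2",
                electron_acceptor = "A")
  b <- reaction("b", "C(aq) + H2(g) -> D(aq) + E(aq)", dg0_prime = -50,
                reference_species = "H2", electron_donor = "H2",
                electron_acceptor = "C")
  conds <- condition_set(c(A = 1e-3, B = 2e-4, C = 5e-2, D = 1e-6,
                           E = 3e-1, H2 = 1e-5))
  ab <- couple_reactions(a, 1, b, 3)
  expect_equal(reaction_quotient(ab, conds),
               reaction_quotient(a, conds) * reaction_quotient(b, conds)^3)
})

test_that("coupling with rational weights keeps coefficients exact", {
  a <- reaction("a", "A(aq) + 3 H2(g) -> B(aq)", dg0_prime = -10,
                reference_species = "H2", electron_donor = "H2")
  b <- reaction("b", "C(aq) + H2(g) -> D(aq)", dg0_prime = -20,
                reference_species = "H2", electron_donor = "H2")
  # 1/3 is inexact in binary yet the combined coefficient of H2 must
  # vanish exactly under rational arithmetic
  ab <- couple_reactions(a, "1/3", b, -1)
  expect_false("H2" %in% ab$species)
  expect_equal(coef(ab)[["A"]], -1 / 3)
  expect_identical(ab$den[ab$species == "A"], 3)
})
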
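test_that("dG' evaluation reproduces the tabulated coupled-reaction values", {
  bundle <- scenario_bundle()
  env <- bundle$conditions$env_coupled
  # environmental free energies of CH4 oxidation coupled to each
  # acceptor, kJ per mol CH4, at the 0.1 kJ precision they are reported
  expected <- c(coupled_sulfate = -5.0, coupled_2cp = -486.2,
                coupled_mcb = -499.3, coupled_pce = -574.0,
                coupled_tce = -568.8, coupled_dca = -839.5)
  for (id in names(expected)) {
    res <- delta_g_prime(bundle$reactions$coupled[[id]], env,
                         basis = "per_reference")
    expect_equal(round(res$value, 1), expected[[id]], info = id)
  }

  # Q = 1 at standard state: dG' collapses onto dG0' exactly
  r <- bundle$reactions$coupled$coupled_sulfate
  res <- delta_g_prime(r, bundle$conditions$standard)
  expect_equal(res$dg_prime[["per_reaction"]], res$dg0_prime[["per_reaction"]])
})

test_that("normalisation bases are mutually consistent", {
  bundle <- scenario_bundle()
  env <- bundle$conditions$env_coupled
  for (r in bundle$reactions$coupled) {
    res <- delta_g_prime(r, env)
    nu <- coef(r)
    expect_equal(res$dg_prime[["per_electron"]] * r$n_electrons,
                 res$dg_prime[["per_reaction"]], tolerance = 1e-12)
    expect_equal(res$dg_prime[["per_acceptor"]] * abs(nu[[r$electron_acceptor]]),
                 res$dg_prime[["per_reaction"]], tolerance = 1e-12)
    expect_equal(res$dg_prime[["per_reference"]] * abs(nu[[r$reference_species]]),
                 res$dg_prime[["per_reaction"]], tolerance = 1e-12)
  }
})

test_that("redox potentials follow dG0' = -nF dE0'", {
  bundle <- scenario_bundle()
  e0 <- vapply(bundle$reactions$h2, redox_potential, numeric(1))
  expect_equal(round(e0[["nitrate_reduction"]], 2), 0.82)
  expect_equal(round(e0[["pce_to_tce"]], 2), 0.90)
  expect_equal(round(e0[["aom"]], 2), -0.18)

  zero <- reaction("z", "A(aq) + H2(g) -> B(aq)", dg0_prime = 0,
                   reference_species = "H2", electron_donor = "H2")
  expect_equal(redox_potential(zero), 0)
  nolec <- reaction("n", "A(aq) -> B(aq)", dg0_prime = -5)
  expect_error(redox_potential(nolec), "n_electrons")
})

test_that("Henry conversion and its round trip", {
  # H2 at 1 atm dissolves to ~7.9e-4 M
  expect_equal(henry_convert(1, 7.8e-6), 7.8e-6 * 101325 / 1000)
  expect_equal(signif(henry_convert(1, 7.8e-6), 3), 7.90e-4)
  expect_equal(henry_convert(0, 7.8e-6), 0)
  x <- c(1e-9, 3.7e-5, 2.2)
  expect_equal(henry_convert(henry_convert(x, 1.4e-5), 1.4e-5, "M_to_atm"),
               x, tolerance = 1e-12)
  reg <- scenario_bundle()$registry
  expect_equal(henry_convert(1, "CH4", registry = reg),
               henry_convert(1, 1.4e-5))
  expect_error(henry_convert(1, "PCE", registry = reg), "Henry")
})

test_that("closed-form H2 thresholds match the bisection oracle", {
  sr <- sulfate_reduction_rxn()
  mg <- methanogenesis_rxn()
  std_sr <- standard_conditions_for(sr)
  std_mg <- standard_conditions_for(mg)

  # frozen from the bisection oracle (200 iterations on log10 a_H2)
  th_sr <- h2_threshold(sr, std_sr, dg_min = -10, basis = "per_mol_h2")
  expect_equal(th_sr$h2_atm, 1.255219e-5, tolerance = 1e-6)
  expect_equal(th_sr$h2_molar, 9.920431e-9, tolerance = 1e-6)
  th_mg <- h2_threshold(mg, std_mg, dg_min = -10, basis = "per_mol_h2")
  expect_equal(th_mg$h2_atm, 6.628699e-5, tolerance = 1e-6)
  expect_equal(th_mg$h2_molar, 5.238893e-8, tolerance = 1e-6)

  # live cross-check at full precision
  expect_equal(th_sr$h2_atm, bisect_h2(sr, std_sr, -40), tolerance = 1e-9)
  expect_equal(th_mg$h2_atm, bisect_h2(mg, std_mg, -40), tolerance = 1e-9)

  # a reaction with dG0' = -10 per mol H2 and unit activities is at its
  # threshold exactly at 1 atm
  unit <- reaction("u", "A(aq) + H2(g) -> B(aq)", dg0_prime = -10,
                   reference_species = "H2", electron_donor = "H2",
                   electron_acceptor = "A")
  th <- h2_threshold(unit, condition_set(c(A = 1, B = 1)))
  expect_equal(th$h2_atm, 1)

  # evaluating dG' at the threshold returns dg_min on the stated basis
  conds_at <- set_activity(std_sr, "H2", th_sr$h2_atm)
  dg <- delta_g_prime(sr, conds_at)$dg_prime[["per_reaction"]] / 4
  expect_equal(dg, -10, tolerance = 1e-9)

  # basis bookkeeping: per_reaction target of -40 equals per-H2 -10
  th_rxn <- h2_threshold(sr, std_sr, dg_min = -40, basis = "per_reaction")
  expect_equal(th_rxn$h2_atm, th_sr$h2_atm)

  expect_error(h2_threshold(aom_reaction(), std_mg), "consume")
  no_h2 <- reaction("x", "A(aq) -> B(aq)", dg0_prime = -5)
  expect_error(h2_threshold(no_h2, std_sr), "H2")
})

test_that("the AOM H2 ceiling matches its oracle and is monotone in CH4", {
  bc <- scenario_bundle()$conditions$aom_breakpoint
  ceil <- aom_h2_ceiling(bc, dg_min = -10)
  # frozen from the bisection oracle; note this does NOT recover the
  # 29.7 uM literature breaking point (see the methods vignette)
  expect_equal(ceil$h2_atm, 1.372988e-6, tolerance = 1e-6)
  expect_equal(ceil$h2_atm, bisect_h2(aom_reaction(), bc, -10),
               tolerance = 1e-9)

  # with dg_min = dG0' and equal CH4/HCO3- activities the ceiling is 1 atm
  eq <- condition_set(c(CH4 = 0.5, `HCO3-` = 0.5))
  expect_equal(aom_h2_ceiling(eq, dg_min = 135.4)$h2_atm, 1)

  # strictly increasing in the CH4 activity
  ceilings <- vapply(c(0.1, 1, 2.14, 10), function(p) {
    aom_h2_ceiling(set_activity(bc, "CH4", p))$h2_atm
  }, numeric(1))
  expect_true(all(diff(ceilings) > 0))

  expect_error(aom_h2_ceiling(condition_set(c(CH4 = 1))), "HCO3-")
})

test_that("syntrophy windows intersect floor and ceiling correctly", {
  bundle <- scenario_bundle()
  env <- bundle$conditions$env_profiles
  pce <- bundle$reactions$h2$pce_to_tce

  w <- syntrophy_window(pce, env, dg_min = -10)
  expect_true(w$feasible)
  expect_lt(w$floor_h2, w$ceiling_h2)
  # dechlorination holds H2 many orders of magnitude below the AOM ceiling
  expect_lt(w$floor_h2 / w$ceiling_h2, 1e-15)

  # an endergonic consumer cannot partner
  bad <- reaction("bad", "A(aq) + H2(g) -> B(aq)", dg0_prime = 100,
                  reference_species = "H2", electron_donor = "H2",
                  electron_acceptor = "A")
  env_bad <- condition_set(c(A = 1, B = 1, CH4 = 3e-5, `HCO3-` = 2.02e-2))
  expect_false(syntrophy_window(bad, env_bad, dg_min = -10)$feasible)

  # boundary: a consumer whose floor sits exactly at the ceiling
  ceil <- aom_h2_ceiling(env_bad, dg_min = -10)
  dg0_boundary <- .R_KJ_TEST * 298.15 * log(ceil$h2_atm) - 10
  boundary <- reaction("edge", "A(aq) + H2(g) -> B(aq)",
                       dg0_prime = dg0_boundary, reference_species = "H2",
                       electron_donor = "H2", electron_acceptor = "A")
  w_edge <- syntrophy_window(boundary, env_bad, dg_min = -10)
  expect_equal(w_edge$floor_h2, w_edge$ceiling_h2, tolerance = 1e-12)
  expect_true(w_edge$feasible)
})

test_that("the energy ladder orders electron-accepting processes", {
  bundle <- scenario_bundle()
  rungs <- bundle$reactions$h2[c("acetogenesis", "methanogenesis",
                                 "sulfate_reduction", "iron_reduction",
                                 "nitrate_reduction", "pce_to_tce")]
  ladder <- energy_ladder(rungs, bundle$conditions$standard,
                          basis = "per_electron")
  expect_equal(ladder$id,
               c("pce_to_tce", "nitrate_reduction", "iron_reduction",
                 "sulfate_reduction", "methanogenesis", "acetogenesis"))
  expect_equal(round(ladder$dg_kj, 1),
               c(-86.7, -79.0, -22.3, -19.0, -16.9, -13.0))

  single <- energy_ladder(rungs[1], bundle$conditions$standard)
  expect_equal(nrow(single), 1)

  # duplicate energies: ties broken lexicographically by id
  dup1 <- rungs$sulfate_reduction
  dup2 <- rungs$sulfate_reduction
  dup1$id <- "b_dup"
  dup2$id <- "a_dup"
  tie <- energy_ladder(list(dup1, dup2), bundle$conditions$standard)
  expect_equal(tie$id, c("a_dup", "b_dup"))
})

test_that("dG'-vs-H2 profiles are monotone and cross thresholds on grid", {
  bundle <- scenario_bundle()
  env <- bundle$conditions$env_profiles
  sr <- bundle$reactions$h2$sulfate_reduction
  grid <- 10^seq(-12, -2, by = 0.05)

  cv <- profile_curve(sr, env, grid, basis = "per_acceptor")
  expect_true(all(diff(cv$dg_kj) < 0)) # consumer: more H2, more favourable

  aom_cv <- profile_curve(bundle$reactions$h2$aom, env, grid,
                          basis = "per_reference")
  expect_true(all(diff(aom_cv$dg_kj) > 0)) # producer: more H2, less favourable

  # the -40 kJ/mol-acceptor crossing interpolates to the closed form
  th <- h2_threshold(sr, env, dg_min = -10, basis = "per_mol_h2")
  below <- max(which(cv$dg_kj > -40))
  expect_true(cv$h2_M[below] <= th$h2_molar &&
                th$h2_molar <= cv$h2_M[below + 1])

  # a single grid point is one delta_g_prime evaluation
  one <- profile_curve(sr, env, 1e-8, basis = "per_acceptor")
  conds1 <- set_activity(env, "H2", henry_convert(1e-8, 7.8e-6, "M_to_atm"))
  expect_equal(one$dg_kj, delta_g_prime(sr, conds1, "per_acceptor")$value)

  # reversal antisymmetry along the whole curve
  rev_cv <- profile_curve(reverse_reaction(sr), env, grid, basis = "per_reaction")
  fwd_cv <- profile_curve(sr, env, grid, basis = "per_reaction")
  expect_equal(rev_cv$dg_kj, -fwd_cv$dg_kj)

  expect_error(profile_curve(sr, env, c(1e-3, 1e-5)), "increasing")
  expect_error(profile_curve(sr, env, c(-1e-3, 1e-5)), "positive")
})
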
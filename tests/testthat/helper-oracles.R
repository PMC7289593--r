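.R_KJ_TEST <- 8.314e-3

# coefficients in name order, for order-insensitive stoichiometry checks
nu_sorted <- function(r) {
  nu <- coef(r)
  nu[order(names(nu))]
}

# Independent root-finding oracle for H2 thresholds: bisection on
# log10(a_H2) over [-30, 2] against delta_g_prime(), never touching the
# closed form under test. Works for both H2 consumers (dG' decreasing in
# a_H2... increasing, since less H2 = more favourable) and producers.
# The bracket spans far beyond any physical H2 level on both sides:
# generated dechlorination-strength consumers can hold thresholds near
# 1e-100 atm, and an ultra-dilute acceptor can push them above 1e+10 atm.
bisect_h2 <- function(reaction, conditions, dg_target_rxn,
                      lo = -150, hi = 60, iterations = 200) {
  dg_at <- function(log10_a) {
    conds <- set_activity(conditions, "H2", 10^log10_a)
    delta_g_prime(reaction, conds, basis = "per_reaction")$value
  }
  f_lo <- dg_at(lo) - dg_target_rxn
  f_hi <- dg_at(hi) - dg_target_rxn
  if (sign(f_lo) == sign(f_hi)) stop("no sign change on bracket")
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    f_mid <- dg_at(mid) - dg_target_rxn
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  10^((lo + hi) / 2)
}

# standard-state conditions (solutes 1 M, gases 1 atm) for a reaction
standard_conditions_for <- function(reaction, temperature = 298.15, pH = 7) {
  sp <- reaction$species[!reaction$phase %in% c("water", "solid") &
                           reaction$species != "H+"]
  condition_set(stats::setNames(rep(1, length(sp)), sp),
                temperature = temperature, pH = pH)
}

sulfate_reduction_rxn <- function() {
  reaction("sulfate_reduction",
           "SO4-2(aq) + 4 H2(g) + 2 H+(aq) -> H2S(aq) + 4 H2O(w)",
           dg0_prime = -151.9, reference_species = "SO4-2",
           electron_donor = "H2", electron_acceptor = "SO4-2")
}

methanogenesis_rxn <- function() {
  reaction("methanogenesis",
           "HCO3-(aq) + 4 H2(g) + H+(aq) -> CH4(g) + 3 H2O(w)",
           dg0_prime = -135.4, reference_species = "HCO3-",
           electron_donor = "H2", electron_acceptor = "HCO3-")
}
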
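# Free-energy evaluation, redox potentials, H2 thresholds and ceilings,
# syntrophy windows, energy ladders and dG'-vs-[H2] profiles.

.BASES <- c("per_reaction", "per_reference", "per_acceptor", "per_electron")

#' Gibbs free-energy change under environmental conditions
#'
#' Evaluates dG' = dG0' + RT ln Q for a reaction at the activities,
#' temperature and pH of a condition set, where Q is the reaction
#' quotient relative to the pH-7 standard state (see
#' [reaction_quotient()]) and RT is in kJ/mol. The result carries the
#' free energy on every normalisation basis: per occurrence of the
#' reaction as written, per mole of the reference species, per mole of
#' electron acceptor, and per mole of electrons, along with the standard
#' redox potential E0' = -dG0'/(nF).
#'
#' @param reaction A [reaction] with a finite `dg0_prime`.
#' @param conditions A [condition_set].
#' @param basis Normalisation basis selecting the headline `value`:
#'   one of `"per_reaction"`, `"per_reference"`, `"per_acceptor"`,
#'   `"per_electron"`.
#' @return An object of class `energy_result`: a list with the chosen
#'   `value`, `basis`, `dg_prime` and `dg0_prime` vectors over all bases,
#'   `e0_prime` (volts), and `temperature` (K).
#' @export
#' @examples
#' r <- reaction("aom_sulfate",
#'   "CH4(g) + SO4-2(aq) + H+(aq) -> HCO3-(aq) + H2S(aq) + H2O(w)",
#'   dg0_prime = -16.5, reference_species = "CH4",
#'   electron_donor = "CH4", electron_acceptor = "SO4-2")
#' env <- condition_set(c(`HCO3-` = 2.02e-2, H2S = 8e-4,
#'                        CH4 = 3e-5, `SO4-2` = 5.2e-3))
#' delta_g_prime(r, env, basis = "per_reference")
delta_g_prime <- function(reaction, conditions,
                          basis = c("per_reaction", "per_reference",
                                    "per_acceptor", "per_electron")) {
  basis <- match.arg(basis)
  stopifnot(inherits(reaction, "reaction"), inherits(conditions, "condition_set"))
  if (length(reaction$species) == 0) {
    # fully cancelled reaction: all energies are zero
    zero <- stats::setNames(rep(0, 4), .BASES)
    return(structure(list(value = 0, basis = basis, dg_prime = zero,
                          dg0_prime = zero, e0_prime = NA_real_,
                          temperature = conditions$temperature),
                     class = "energy_result"))
  }
  if (is.na(reaction$dg0_prime)) stop("reaction has no dg0_prime: ", reaction$id)
  rt <- .R_KJ * conditions$temperature
  dg0_rxn <- dg0_reaction(reaction)
  dg_rxn <- dg0_rxn + rt * .ln_reaction_quotient(reaction, conditions)
  nu <- coef(reaction)
  nu_ref <- abs(nu[[reaction$reference_species]])
  nu_ea <- if (is.null(reaction$electron_acceptor)) NA_real_ else
    abs(nu[[reaction$electron_acceptor]])
  n_e <- reaction$n_electrons
  if (basis == "per_acceptor" && is.na(nu_ea)) {
    stop("no electron acceptor designated for reaction: ", reaction$id)
  }
  if (basis == "per_electron" && (is.na(n_e) || n_e <= 0)) {
    stop("n_electrons unset or non-positive for reaction: ", reaction$id)
  }
  divisors <- c(per_reaction = 1, per_reference = nu_ref,
                per_acceptor = nu_ea, per_electron = n_e)
  dg_prime <- dg_rxn / divisors
  dg0 <- dg0_rxn / divisors
  e0 <- if (is.na(n_e) || n_e <= 0) NA_real_ else
    -(dg0_rxn / n_e) / .FARADAY_KJ_V
  structure(
    list(value = unname(dg_prime[basis]), basis = basis,
         dg_prime = dg_prime, dg0_prime = dg0, e0_prime = e0,
         temperature = conditions$temperature),
    class = "energy_result"
  )
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> dG' = %.3f kJ (%s), T = %.2f K\n",
              x$value, x$basis, x$temperature))
  df <- data.frame(basis = .BASES,
                   dg_prime_kj = unname(x$dg_prime[.BASES]),
                   dg0_prime_kj = unname(x$dg0_prime[.BASES]))
  print(df, row.names = FALSE)
  if (!is.na(x$e0_prime)) cat(sprintf("E0' = %.3f V\n", x$e0_prime))
  invisible(x)
}

#' Standard redox potential from the free energy
#'
#' E0' = -dG0' / (n F) with F = 96.5 kJ/V, where dG0' is the standard
#' pH-7 free-energy change per occurrence of the reaction and n the
#' number of electrons transferred.
#'
#' @param reaction A [reaction] with `n_electrons` set.
#' @return E0' in volts.
#' @export
redox_potential <- function(reaction) {
  stopifnot(inherits(reaction, "reaction"))
  n <- reaction$n_electrons
  if (is.na(n) || n <= 0) {
    stop("n_electrons unset or non-positive for reaction: ", reaction$id)
  }
  -(dg0_reaction(reaction) / n) / .FARADAY_KJ_V
}

#' Convert a gas between partial pressure and aqueous concentration
#'
#' Henry's law with the constant in mol m^-3 Pa^-1:
#' `M = atm * 101325 * K_H / 1000`, and the inverse for M -> atm.
#'
#' @param value Numeric vector of partial pressures (atm) or
#'   concentrations (M).
#' @param species Either a numeric Henry constant (mol m^-3 Pa^-1), a
#'   species name to look up in `registry`, or a one-row subset of a
#'   [species_registry].
#' @param direction `"atm_to_M"` or `"M_to_atm"`.
#' @param registry A [species_registry], required when `species` is a
#'   name.
#' @return Converted numeric vector.
#' @export
#' @examples
#' henry_convert(1, 7.8e-6)            # H2 solubility at 1 atm, ~7.9e-4 M
#' henry_convert(2.97e-5, 7.8e-6, "M_to_atm")
henry_convert <- function(value, species, direction = c("atm_to_M", "M_to_atm"),
                          registry = NULL) {
  direction <- match.arg(direction)
  k_h <- .resolve_henry(species, registry)
  if (direction == "atm_to_M") {
    value * .ATM_PA * k_h / 1000
  } else {
    value * 1000 / (.ATM_PA * k_h)
  }
}

.resolve_henry <- function(species, registry = NULL) {
  if (is.numeric(species)) {
    k_h <- species
  } else if (is.character(species)) {
    if (is.null(registry)) stop("a species_registry is needed to look up ", species)
    k_h <- .registry_lookup(registry, species)$henry_mol_m3_Pa
  } else if (is.data.frame(species)) {
    k_h <- species$henry_mol_m3_Pa[1]
  } else {
    stop("cannot interpret 'species' as a Henry constant")
  }
  if (length(k_h) != 1 || is.na(k_h) || k_h <= 0) {
    stop("species has no (positive) Henry constant")
  }
  k_h
}

# Convert a dG target on a user basis to kJ per occurrence of `reaction`
.dg_to_per_reaction <- function(reaction, dg, basis) {
  nu <- coef(reaction)
  mult <- switch(
    basis,
    per_reaction = 1,
    per_mol_h2 = {
      if (!"H2" %in% reaction$species) stop("reaction does not contain H2")
      abs(nu[["H2"]])
    },
    per_reference = abs(nu[[reaction$reference_species]]),
    per_acceptor = {
      if (is.null(reaction$electron_acceptor)) {
        stop("no electron acceptor designated for reaction: ", reaction$id)
      }
      abs(nu[[reaction$electron_acceptor]])
    },
    stop("unknown basis: ", basis)
  )
  dg * mult
}

# closed-form a_H2 solving dG'(a_H2) = dg_target (per occurrence)
.solve_h2_activity <- function(reaction, conditions, dg_target_rxn) {
  nu <- coef(reaction)
  if (!"H2" %in% reaction$species || nu[["H2"]] == 0) {
    stop("reaction does not contain H2: ", reaction$id)
  }
  rt <- .R_KJ * conditions$temperature
  ln_q_other <- .ln_reaction_quotient(reaction, conditions, skip = "H2")
  ln_a <- ((dg_target_rxn - dg0_reaction(reaction)) / rt - ln_q_other) / nu[["H2"]]
  exp(ln_a)
}

.threshold_result <- function(h2_atm, k_h, dg_min, basis, kind) {
  structure(
    list(h2_atm = h2_atm, h2_molar = henry_convert(h2_atm, k_h),
         dg_min = dg_min, basis = basis, k_h = k_h, kind = kind),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s H2 = %.4g atm = %.4g M (dG' = %g kJ %s)\n",
              x$kind, x$h2_atm, x$h2_molar, x$dg_min, x$basis))
  invisible(x)
}

#' H2 consumption threshold of an H2-consuming reaction
#'
#' The lowest H2 activity at which the reaction still yields at least
#' `dg_min` on the requested basis: solved in closed form from
#' dG' = dG0' + RT ln Q by isolating the H2 activity. Returned both as
#' partial pressure (atm) and, via Henry's law, as aqueous concentration
#' (M). Any H2 activity present in `conditions` is ignored; all other
#' gas/aqueous species must be covered.
#'
#' @param reaction A [reaction] consuming H2 (negative H2 coefficient).
#' @param conditions A [condition_set] for the non-H2 species.
#' @param dg_min Minimum free-energy yield, kJ/mol on `basis`
#'   (default -10, the canonical minimum for microbial energy
#'   conservation).
#' @param basis Basis of `dg_min`: `"per_mol_h2"` (default),
#'   `"per_reaction"` or `"per_acceptor"`. There is no silent default
#'   conversion between bases.
#' @param k_h Henry constant for H2, mol m^-3 Pa^-1.
#' @return An object of class `threshold_result` with fields `h2_atm`,
#'   `h2_molar`, `dg_min`, `basis`.
#' @export
#' @examples
#' sr <- reaction("sr", "SO4-2(aq) + 4 H2(g) + 2 H+(aq) -> H2S(aq) + 4 H2O(w)",
#'                dg0_prime = -151.9, reference_species = "SO4-2",
#'                electron_donor = "H2", electron_acceptor = "SO4-2")
#' std <- condition_set(c(`SO4-2` = 1, H2S = 1))
#' h2_threshold(sr, std)  # ~1.3e-5 atm, ~1e-8 M
h2_threshold <- function(reaction, conditions, dg_min = -10,
                         basis = c("per_mol_h2", "per_reaction", "per_acceptor"),
                         k_h = .HENRY_H2) {
  basis <- match.arg(basis)
  nu <- coef(reaction)
  if (!"H2" %in% reaction$species || nu[["H2"]] >= 0) {
    stop("reaction does not consume H2: ", reaction$id)
  }
  dg_target <- .dg_to_per_reaction(reaction, dg_min, basis)
  h2_atm <- .solve_h2_activity(reaction, conditions, dg_target)
  .threshold_result(h2_atm, k_h, dg_min, basis, kind = "consumption threshold")
}

#' H2 ceiling for anaerobic oxidation of methane
#'
#' AOM (CH4 + 3 H2O -> HCO3- + 4 H2 + H+, dG0' = +135.4 kJ/mol CH4) is
#' endergonic under standard conditions and becomes feasible only when
#' the H2 it produces is held low. This computes the maximum H2 activity
#' at which AOM still yields at least `dg_min` kJ per mol CH4:
#' `a_H2 = ((a_CH4 / a_HCO3-) * exp((dG' - dG0') / RT))^(1/4)` (with the
#' proton term entering at pH != 7).
#'
#' @param conditions A [condition_set] supplying `CH4` and `HCO3-`
#'   activities.
#' @param dg_min Required yield, kJ per mol CH4 (default -10).
#' @param dg0_prime Standard free energy of AOM, kJ/mol CH4.
#' @param k_h Henry constant for H2, mol m^-3 Pa^-1.
#' @return A `threshold_result` (fields `h2_atm`, `h2_molar`).
#' @export
#' @examples
#' aom_h2_ceiling(condition_set(c(CH4 = 2.14, `HCO3-` = 2.02e-2)))
aom_h2_ceiling <- function(conditions, dg_min = -10, dg0_prime = 135.4,
                           k_h = .HENRY_H2) {
  r <- aom_reaction(dg0_prime)
  h2_atm <- .solve_h2_activity(r, conditions, dg_min)
  .threshold_result(h2_atm, k_h, dg_min, basis = "per_mol_ch4",
                    kind = "production ceiling")
}

#' The canonical AOM half-process
#'
#' CH4 oxidation to bicarbonate written as an H2-producing half-process.
#'
#' @param dg0_prime Standard pH-7 free energy, kJ per mol CH4.
#' @return A [reaction].
#' @export
aom_reaction <- function(dg0_prime = 135.4) {
  reaction("aom", "CH4(g) + 3 H2O(w) -> HCO3-(aq) + 4 H2(g) + H+(aq)",
           dg0_prime = dg0_prime, reference_species = "CH4",
           electron_donor = "CH4", n_electrons = 8)
}

#' Feasibility window for H2-mediated syntrophy with AOM
#'
#' Intersects the H2 ceiling of the methane-oxidising producer with the
#' H2 consumption threshold (floor) of an H2-consuming partner. The
#' partnership is thermodynamically feasible when the floor lies at or
#' below the ceiling: in that interval both organisms clear the minimum
#' energy quantum.
#'
#' @param consumer A [reaction] consuming H2.
#' @param conditions A [condition_set] covering both processes (CH4 and
#'   HCO3- for the producer; the consumer's species).
#' @param dg_min Minimum yield for the consumer, kJ/mol on
#'   `consumer_basis` (default -10).
#' @param consumer_basis Basis of the consumer's `dg_min`
#'   (default `"per_mol_h2"`).
#' @param producer_dg_min Minimum yield for the producer, kJ per mol CH4.
#' @param producer_dg0 Standard free energy of the producer half-process.
#' @param k_h Henry constant for H2.
#' @return An object of class `syntrophy_window` with `floor_h2`,
#'   `ceiling_h2` (both in M), `floor`, `ceiling` (threshold_result) and
#'   `feasible`.
#' @export
syntrophy_window <- function(consumer, conditions, dg_min = -10,
                             consumer_basis = "per_mol_h2",
                             producer_dg_min = dg_min,
                             producer_dg0 = 135.4, k_h = .HENRY_H2) {
  floor_res <- h2_threshold(consumer, conditions, dg_min = dg_min,
                            basis = consumer_basis, k_h = k_h)
  ceiling_res <- aom_h2_ceiling(conditions, dg_min = producer_dg_min,
                                dg0_prime = producer_dg0, k_h = k_h)
  structure(
    list(floor_h2 = floor_res$h2_molar, ceiling_h2 = ceiling_res$h2_molar,
         floor = floor_res, ceiling = ceiling_res,
         feasible = floor_res$h2_molar <= ceiling_res$h2_molar),
    class = "syntrophy_window"
  )
}

#' @export
print.syntrophy_window <- function(x, ...) {
  cat(sprintf("<syntrophy_window> floor %.4g M, ceiling %.4g M: %s\n",
              x$floor_h2, x$ceiling_h2,
              if (x$feasible) "FEASIBLE" else "infeasible"))
  invisible(x)
}

#' Rank reactions on the energy ladder
#'
#' Evaluates dG' for each reaction under shared conditions and sorts
#' ascending (most exergonic first). Ties are broken by reaction id.
#' Fully cancelled (empty) reactions are excluded.
#'
#' @param reactions List of [reaction] objects.
#' @param conditions A [condition_set].
#' @param basis Normalisation basis (default `"per_electron"`, the
#'   conventional scale for comparing electron-accepting processes).
#' @return A data.frame with columns `rank`, `id`, `dg_kj`.
#' @export
energy_ladder <- function(reactions, conditions,
                          basis = c("per_electron", "per_reaction",
                                    "per_reference", "per_acceptor")) {
  basis <- match.arg(basis)
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  reactions <- Filter(function(r) length(r$species) > 0, reactions)
  if (length(reactions) == 0) {
    return(data.frame(rank = integer(), id = character(), dg_kj = numeric()))
  }
  dg <- vapply(reactions, function(r)
    delta_g_prime(r, conditions, basis = basis)$value, numeric(1))
  ids <- vapply(reactions, `[[`, character(1), "id")
  ord <- order(dg, ids, method = "radix")
  data.frame(rank = seq_along(ord), id = unname(ids[ord]),
             dg_kj = unname(dg[ord]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Free-energy profile versus H2 concentration
#'
#' Evaluates dG' along a grid of aqueous H2 concentrations: each grid
#' point is converted M -> atm via Henry's law, substituted as the H2
#' activity, and the reaction evaluated on the requested basis. For an
#' H2 consumer the curve decreases with rising H2; for an H2 producer
#' such as AOM it increases.
#'
#' @param reaction A [reaction] containing H2 on either side.
#' @param conditions A [condition_set] for all non-H2 species.
#' @param h2_grid Strictly positive, increasing vector of H2
#'   concentrations (M).
#' @param basis Normalisation basis (default `"per_acceptor"`, the scale
#'   used for comparing consumption curves; use `"per_reference"` for
#'   the AOM producer curve).
#' @param k_h Henry constant for H2.
#' @return A data.frame with columns `h2_M`, `h2_atm`, `dg_kj`.
#' @export
profile_curve <- function(reaction, conditions, h2_grid,
                          basis = c("per_acceptor", "per_reaction",
                                    "per_reference", "per_electron"),
                          k_h = .HENRY_H2) {
  basis <- match.arg(basis)
  stopifnot(inherits(reaction, "reaction"))
  if (!"H2" %in% reaction$species) {
    stop("reaction does not contain H2: ", reaction$id)
  }
  if (any(!is.finite(h2_grid)) || any(h2_grid <= 0)) {
    stop("h2_grid must be strictly positive")
  }
  if (is.unsorted(h2_grid, strictly = TRUE)) {
    stop("h2_grid must be strictly increasing")
  }
  h2_atm <- henry_convert(h2_grid, k_h, "M_to_atm")
  dg <- vapply(h2_atm, function(p) {
    delta_g_prime(reaction, set_activity(conditions, "H2", p), basis = basis)$value
  }, numeric(1))
  data.frame(h2_M = h2_grid, h2_atm = h2_atm, dg_kj = dg)
}
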
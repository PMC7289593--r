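# Seeded generator of random-but-valid H2-consuming reactions and
# condition sets, used for property-based testing of the energetics
# without any external input.

#' Configuration for the synthetic scenario generator
#'
#' @param seed Integer seed; together with the documented generation
#'   order it fully determines the output.
#' @param n_species Number of candidate product species.
#' @param dg0_range Interval (kJ per mol H2) the standard free energy is
#'   drawn from uniformly. The default spans the range observed across
#'   anaerobic hydrogenotrophic respirations, from acetogenesis (about
#'   -26 kJ/mol H2) to reductive dechlorination (about -193 kJ/mol H2).
#' @param activity_log10_range Interval of log10 activities for
#'   [random_conditions()]; the default \[-9, 0\] spans nanomolar trace
#'   compounds to 1 M / 1 atm.
#' @param max_stoich Largest coefficient for acceptor/product species.
#' @param fraction_gas Probability a generated species is a gas.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed, n_species = 6, dg0_range = c(-193, -26),
                             activity_log10_range = c(-9, 0),
                             max_stoich = 4, fraction_gas = 0.25) {
  stopifnot(length(seed) == 1, is.finite(seed),
            length(dg0_range) == 2, dg0_range[1] <= dg0_range[2],
            length(activity_log10_range) == 2,
            activity_log10_range[1] <= activity_log10_range[2],
            max_stoich >= 1, fraction_gas >= 0, fraction_gas <= 1,
            n_species >= 2)
  structure(
    list(seed = as.integer(seed), n_species = n_species,
         dg0_range = dg0_range,
         activity_log10_range = activity_log10_range,
         max_stoich = as.integer(max_stoich), fraction_gas = fraction_gas),
    class = "generator_config"
  )
}

# run expr with the generator's own RNG stream, restoring the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a random H2-consuming reaction
#'
#' Draws a charge-balanced reaction of the canonical shape
#' `a EA + b H2 -> c C + d D`: one designated electron acceptor, `b` in
#' 1..4 moles of H2, one or two neutral products, coefficients up to
#' `max_stoich`, and a standard free energy drawn uniformly from
#' `dg0_range` (kJ per mol H2). All generated species are electrically
#' neutral, so charge balance holds by construction, and
#' `n_electrons = 2 b` by the H2 donor rule.
#'
#' Generation order (fixed for reproducibility): `b`, acceptor
#' coefficient `a`, number of products, product coefficients, phase of
#' each species (gas with probability `fraction_gas`, else aqueous),
#' then `dg0`.
#'
#' @param config A [generator_config].
#' @param id Identifier for the reaction.
#' @return A [reaction] consuming H2, with reference species H2 and
#'   `dg0_prime` in kJ per mol H2.
#' @export
#' @examples
#' random_consumer_reaction(generator_config(seed = 1))
random_consumer_reaction <- function(config, id = sprintf("synth_%d", config$seed)) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    b <- sample(1:4, 1)
    a_coef <- sample(seq_len(config$max_stoich), 1)
    n_prod <- sample(1:2, 1)
    p_coef <- sample(seq_len(config$max_stoich), n_prod, replace = TRUE)
    species <- c("EA", "H2", paste0("P", seq_len(n_prod)))
    n_sp <- length(species)
    gas <- stats::runif(n_sp) < config$fraction_gas
    phase <- ifelse(gas, "gas", "aqueous")
    phase[species == "H2"] <- "gas"
    dg0 <- stats::runif(1, config$dg0_range[1], config$dg0_range[2])
    stoich <- stats::setNames(c(-a_coef, -b, p_coef), species)
    reaction(id, stoichiometry = stoich,
             phases = stats::setNames(phase, species),
             dg0_prime = dg0, reference_species = "H2",
             electron_donor = "H2", electron_acceptor = "EA",
             n_electrons = 2 * b)
  })
}

#' Generate a random condition set for a collection of species
#'
#' Activities are drawn log-uniformly within `activity_log10_range`
#' (in the order the species are supplied); water and solid species are
#' pinned to activity 1 and consume no random draws. pH is 7 and the
#' temperature 298.15 K.
#'
#' @param config A [generator_config].
#' @param species Character vector of species names, or a [reaction]
#'   whose species are used.
#' @param phases Optional named phase vector (defaults to aqueous; a
#'   [reaction] supplies its own).
#' @return A [condition_set].
#' @export
random_conditions <- function(config, species, phases = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (inherits(species, "reaction")) {
    phases <- stats::setNames(species$phase, species$species)
    species <- species$species
  }
  if (is.null(phases)) {
    phases <- stats::setNames(rep("aqueous", length(species)), species)
  }
  .with_seed(config$seed + 1L, {
    lo <- config$activity_log10_range[1]
    hi <- config$activity_log10_range[2]
    acts <- 10^stats::runif(length(species), lo, hi)
    fixed <- .normalize_phase(phases[species]) %in% c("water", "solid")
    acts[fixed] <- 1
    acts <- stats::setNames(acts, species)
    acts <- acts[!species %in% "H+"]
    condition_set(acts, temperature = 298.15, pH = 7)
  })
}
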
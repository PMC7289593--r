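#' Construct a chemical reaction
#'
#' A reaction is a signed stoichiometry over named species (reactants
#' negative, products positive; coefficients held as exact rationals),
#' together with its standard Gibbs free-energy change at pH 7
#' (`dg0_prime`, in kJ per mole of `reference_species`), the designated
#' electron donor and acceptor, and the number of electrons transferred
#' per occurrence of the reaction as written.
#'
#' `n_electrons` may be omitted for the common donors: it is filled in as
#' 2 electrons per H2 consumed, or 8 per CH4 oxidised to bicarbonate.
#'
#' @param id Reaction identifier string.
#' @param equation Equation string in the mini-grammar of
#'   [parse_equation()]; alternatively supply `stoichiometry` + `phases`.
#' @param stoichiometry Named numeric vector of signed coefficients
#'   (used when `equation` is `NULL`).
#' @param phases Named character vector of phases for `stoichiometry`
#'   species, or a [species_registry] to look them up from.
#' @param dg0_prime Standard Gibbs free-energy change at pH 7, kJ per mol
#'   of `reference_species`.
#' @param reference_species Species whose unit turnover defines the
#'   "per mol" basis of `dg0_prime`. Defaults to the electron donor,
#'   else the first reactant.
#' @param electron_donor,electron_acceptor Optional species names.
#' @param n_electrons Mol electrons transferred per occurrence of the
#'   reaction as written.
#' @return An object of class `reaction`.
#' @export
#' @examples
#' sulfate <- reaction(
#'   "sulfate_reduction",
#'   "SO4-2(aq) + 4 H2(g) + 2 H+(aq) -> H2S(aq) + 4 H2O(w)",
#'   dg0_prime = -151.9, reference_species = "SO4-2",
#'   electron_donor = "H2", electron_acceptor = "SO4-2"
#' )
#' coef(sulfate)
reaction <- function(id, equation = NULL, stoichiometry = NULL, phases = NULL,
                     dg0_prime = NA_real_, reference_species = NULL,
                     electron_donor = NULL, electron_acceptor = NULL,
                     n_electrons = NA_real_) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!is.null(equation)) {
    tab <- parse_equation(equation)
  } else {
    if (is.null(stoichiometry) || is.null(names(stoichiometry))) {
      stop("supply either an equation string or a named stoichiometry")
    }
    if (inherits(phases, "species_registry")) {
      rows <- .registry_lookup(phases, names(stoichiometry))
      ph <- rows$phase
      ch <- rows$charge
    } else {
      if (is.null(phases)) stop("phases are required with a raw stoichiometry")
      ph <- .normalize_phase(unname(phases[names(stoichiometry)]))
      ch <- vapply(names(stoichiometry), .charge_from_name, numeric(1))
    }
    rat <- lapply(unname(stoichiometry), .rationalize)
    tab <- data.frame(
      species = names(stoichiometry), phase = ph, charge = ch,
      num = vapply(rat, `[[`, numeric(1), "num"),
      den = vapply(rat, `[[`, numeric(1), "den"),
      stringsAsFactors = FALSE
    )
  }
  .new_reaction(id, tab, dg0_prime, reference_species,
                electron_donor, electron_acceptor, n_electrons)
}

.new_reaction <- function(id, tab, dg0_prime, reference_species,
                          electron_donor, electron_acceptor, n_electrons,
                          exact = TRUE) {
  named_roles <- c(reference = reference_species, donor = electron_donor,
                   acceptor = electron_acceptor)
  missing_roles <- named_roles[!named_roles %in% tab$species]
  if (length(missing_roles) > 0) {
    stop("species not in stoichiometry: ",
         paste(sprintf("%s (%s)", missing_roles, names(missing_roles)),
               collapse = ", "))
  }
  if (is.null(reference_species)) {
    reference_species <- if (!is.null(electron_donor)) {
      electron_donor
    } else if (any(tab$num < 0)) {
      tab$species[tab$num < 0][1]
    } else {
      NULL
    }
  }
  r <- structure(
    list(
      id = id,
      species = tab$species, phase = tab$phase, charge = tab$charge,
      num = tab$num, den = tab$den,
      dg0_prime = as.numeric(dg0_prime),
      reference_species = reference_species,
      electron_donor = electron_donor,
      electron_acceptor = electron_acceptor,
      n_electrons = as.numeric(n_electrons),
      exact = exact
    ),
    class = "reaction"
  )
  if (is.na(r$n_electrons)) r$n_electrons <- .default_n_electrons(r)
  r
}

# 2 e- per H2 consumed; 8 e- per CH4 oxidised to HCO3-
.default_n_electrons <- function(r) {
  nu <- coef(r)
  if (identical(r$electron_donor, "H2") && "H2" %in% r$species) {
    return(2 * abs(nu[["H2"]]))
  }
  if (identical(r$electron_donor, "CH4") && "CH4" %in% r$species &&
      "HCO3-" %in% r$species) {
    return(8 * abs(nu[["CH4"]]))
  }
  NA_real_
}

#' @export
coef.reaction <- function(object, ...) {
  stats::setNames(object$num / object$den, object$species)
}

#' Per-occurrence standard free energy of a reaction
#'
#' Converts the stored per-reference-mole `dg0_prime` into kJ per
#' occurrence of the reaction as written.
#'
#' @param reaction A [reaction].
#' @return kJ per occurrence (0 for an empty reaction).
#' @export
dg0_reaction <- function(reaction) {
  stopifnot(inherits(reaction, "reaction"))
  if (length(reaction$species) == 0) return(0)
  nu_ref <- abs(coef(reaction)[[reaction$reference_species]])
  reaction$dg0_prime * nu_ref
}

#' @export
print.reaction <- function(x, ...) {
  if (length(x$species) == 0) {
    cat(sprintf("<reaction %s> (empty)\n", x$id))
    return(invisible(x))
  }
  cat(sprintf("<reaction %s>\n  %s\n", x$id, format_equation(x)))
  cat(sprintf("  dG0' = %.4g kJ/mol %s", x$dg0_prime, x$reference_species))
  if (!is.na(x$n_electrons)) cat(sprintf(", n = %g e-", x$n_electrons))
  if (!is.null(x$electron_donor)) cat(", donor ", x$electron_donor, sep = "")
  if (!is.null(x$electron_acceptor)) cat(", acceptor ", x$electron_acceptor, sep = "")
  cat("\n")
  invisible(x)
}

#' Validate a reaction against its invariants
#'
#' Checks that the designated reference/donor/acceptor species carry
#' nonzero coefficients, that total charge balances when all charges are
#' known, that `n_electrons` is positive when set, and that the declared
#' electron count agrees with the donor rule (2 e- per H2; 8 e- per CH4
#' oxidised to bicarbonate). Violations are returned as text, not
#' raised, so exotic chemistries can be inspected rather than rejected.
#'
#' @param reaction A [reaction].
#' @param registry Optional [species_registry]; when supplied, every
#'   species must exist in it (unknown names are an error) and registry
#'   charges/phases override those parsed from names.
#' @return Character vector of violation descriptions (empty when valid).
#' @export
validate_reaction <- function(reaction, registry = NULL) {
  stopifnot(inherits(reaction, "reaction"))
  violations <- character()
  charge <- reaction$charge
  if (!is.null(registry)) {
    rows <- .registry_lookup(registry, reaction$species)
    charge <- rows$charge
  }
  nu <- coef(reaction)
  for (role in c("reference_species", "electron_donor", "electron_acceptor")) {
    sp <- reaction[[role]]
    if (!is.null(sp) && (!sp %in% reaction$species || nu[[sp]] == 0)) {
      violations <- c(violations, sprintf(
        "%s '%s' missing from stoichiometry or has zero coefficient", role, sp))
    }
  }
  if (length(nu) > 0 && !anyNA(charge)) {
    net <- sum(nu * charge)
    if (abs(net) > 1e-9) {
      violations <- c(violations, sprintf(
        "charge imbalance: net charge %+g (species: %s)", net,
        paste(reaction$species[charge != 0], collapse = ", ")))
    }
  }
  if (!is.na(reaction$n_electrons) && reaction$n_electrons <= 0) {
    violations <- c(violations, "n_electrons must be > 0 when set")
  }
  expected_n <- .default_n_electrons(reaction)
  if (!is.na(expected_n) && !is.na(reaction$n_electrons) &&
      abs(reaction$n_electrons - expected_n) > 1e-9) {
    violations <- c(violations, sprintf(
      "electron count %g does not match donor rule for %s (expected %g)",
      reaction$n_electrons, reaction$electron_donor, expected_n))
  }
  violations
}

#' Scale a reaction by a positive factor
#'
#' Multiplies all stoichiometric coefficients, the electron count, and
#' hence the per-occurrence free energy by `factor`. The per-reference
#' `dg0_prime` is unchanged because the reference species scales with
#' everything else. Useful to interconvert e.g. a per-4-H2 reaction and
#' its per-H2 form.
#'
#' @param reaction A [reaction].
#' @param factor Positive scale factor; numeric or a rational string
#'   such as `"1/4"` for exactness.
#' @return The scaled [reaction].
#' @export
scale_reaction <- function(reaction, factor) {
  stopifnot(inherits(reaction, "reaction"))
  f <- .rationalize(factor)
  if (f$num / f$den <= 0) stop("scale factor must be > 0")
  out <- reaction
  if (f$exact && reaction$exact) {
    r <- .rat_mul(reaction$num, reaction$den,
                  rep(f$num, length(reaction$num)),
                  rep(f$den, length(reaction$den)))
    out$num <- r$num
    out$den <- r$den
  } else {
    out$num <- reaction$num / reaction$den * (f$num / f$den)
    out$den <- rep(1, length(reaction$num))
    out$exact <- FALSE
  }
  out$n_electrons <- reaction$n_electrons * f$num / f$den
  out
}

#' Reverse a reaction
#'
#' Negates every coefficient and the free energy, and swaps the electron
#' donor and acceptor.
#'
#' @param reaction A [reaction].
#' @return The reversed [reaction].
#' @export
reverse_reaction <- function(reaction) {
  stopifnot(inherits(reaction, "reaction"))
  out <- reaction
  out$num <- -reaction$num
  out$dg0_prime <- -reaction$dg0_prime
  out$electron_donor <- reaction$electron_acceptor
  out$electron_acceptor <- reaction$electron_donor
  out
}

#' Linearly combine two reactions
#'
#' Forms `weight_a * a + weight_b * b`, cancelling shared species. This
#' is how an H2-producing half-process (such as AOM) is coupled to an
#' H2-consuming partner: with matched weights the H2 cancels and the
#' combined free energy is the weighted sum of the parts.
#'
#' With rational weights the combination is exact and only exact zeros
#' are dropped; with non-rational weights, species whose resulting
#' |coefficient| falls below 1e-12 are removed.
#'
#' @param a,b [reaction] objects.
#' @param weight_a,weight_b Weights; numeric or rational strings.
#' @param id Identifier for the combined reaction.
#' @param reference_species,electron_donor,electron_acceptor Roles of the
#'   combined reaction; defaults carry over from `a` (then `b`) when the
#'   species survives cancellation.
#' @return The combined [reaction]. `n_electrons` is recomputed from the
#'   declared donor when the donor rule applies, otherwise left `NA`.
#' @export
#' @examples
#' aom <- reaction("aom", "CH4(g) + 3 H2O(w) -> HCO3-(aq) + 4 H2(g) + H+(aq)",
#'                 dg0_prime = 135.4, reference_species = "CH4",
#'                 electron_donor = "CH4")
#' sr_h2 <- reaction("sr", "SO4-2(aq) + 4 H2(g) + 2 H+(aq) -> H2S(aq) + 4 H2O(w)",
#'                   dg0_prime = -151.9, reference_species = "SO4-2",
#'                   electron_donor = "H2", electron_acceptor = "SO4-2")
#' couple_reactions(aom, 1, sr_h2, 1, id = "aom_sulfate",
#'                  electron_acceptor = "SO4-2")
couple_reactions <- function(a, weight_a, b, weight_b,
                             id = paste(a$id, b$id, sep = "+"),
                             reference_species = NULL,
                             electron_donor = NULL,
                             electron_acceptor = NULL) {
  stopifnot(inherits(a, "reaction"), inherits(b, "reaction"))
  wa <- .rationalize(weight_a)
  wb <- .rationalize(weight_b)
  if (wa$num == 0 && wb$num == 0) stop("both weights are zero: empty reaction")
  species <- union(a$species, b$species)
  ia <- match(species, a$species)
  ib <- match(species, b$species)
  meta_from <- ifelse(is.na(ia), "b", "a")
  shared <- !is.na(ia) & !is.na(ib)
  if (any(shared)) {
    pa <- a$phase[ia[shared]]
    pb <- b$phase[ib[shared]]
    if (any(pa != pb)) {
      stop("phase mismatch for shared species: ",
           paste(species[shared][pa != pb], collapse = ", "))
    }
  }
  exact <- wa$exact && wb$exact && a$exact && b$exact
  get_rat <- function(r, idx) {
    num <- ifelse(is.na(idx), 0, r$num[idx])
    den <- ifelse(is.na(idx), 1, r$den[idx])
    list(num = num, den = den)
  }
  ra <- get_rat(a, ia)
  rb <- get_rat(b, ib)
  if (exact) {
    ta <- .rat_mul(ra$num, ra$den, rep(wa$num, length(species)),
                   rep(wa$den, length(species)))
    tb <- .rat_mul(rb$num, rb$den, rep(wb$num, length(species)),
                   rep(wb$den, length(species)))
    comb <- .rat_add(ta$num, ta$den, tb$num, tb$den)
    keep <- comb$num != 0
  } else {
    val <- ra$num / ra$den * (wa$num / wa$den) +
      rb$num / rb$den * (wb$num / wb$den)
    comb <- list(num = val, den = rep(1, length(val)))
    keep <- abs(val) >= 1e-12
  }
  phase <- ifelse(meta_from == "a", a$phase[ia], b$phase[ib])
  charge <- ifelse(meta_from == "a", a$charge[ia], b$charge[ib])
  tab <- data.frame(
    species = species[keep], phase = phase[keep], charge = charge[keep],
    num = comb$num[keep], den = comb$den[keep],
    stringsAsFactors = FALSE
  )
  pick_role <- function(explicit, ra_role, rb_role) {
    for (cand in list(explicit, ra_role, rb_role)) {
      if (!is.null(cand) && cand %in% tab$species) return(cand)
    }
    NULL
  }
  reference_species <- pick_role(reference_species, a$reference_species,
                                 b$reference_species)
  electron_donor <- pick_role(electron_donor, a$electron_donor,
                              b$electron_donor)
  electron_acceptor <- pick_role(electron_acceptor, a$electron_acceptor,
                                 b$electron_acceptor)
  dg_rxn <- wa$num / wa$den * dg0_reaction(a) + wb$num / wb$den * dg0_reaction(b)
  if (nrow(tab) == 0) {
    out <- structure(
      list(id = id, species = character(), phase = character(),
           charge = numeric(), num = numeric(), den = numeric(),
           dg0_prime = dg_rxn, reference_species = NULL,
           electron_donor = NULL, electron_acceptor = NULL,
           n_electrons = NA_real_, exact = exact),
      class = "reaction"
    )
    return(out)
  }
  if (is.null(reference_species)) reference_species <- tab$species[tab$num < 0][1]
  nu_ref <- abs(tab$num / tab$den)[match(reference_species, tab$species)]
  .new_reaction(id, tab, dg0_prime = dg_rxn / nu_ref,
                reference_species = reference_species,
                electron_donor = electron_donor,
                electron_acceptor = electron_acceptor,
                n_electrons = NA_real_, exact = exact)
}

#' Reaction quotient at given conditions
#'
#' Computes Q, the product of product activities over reactant activities
#' raised to their stoichiometric coefficients. Water and solid-phase
#' species contribute 1. The proton contributes relative to the pH-7
#' standard state, i.e. as `(a_H+ / 1e-7)^nu`, so that at pH 7 protons
#' drop out entirely -- this is the convention under which tabulated
#' pH-7 standard free energies are corrected to environmental conditions.
#'
#' @param reaction A [reaction].
#' @param conditions A [condition_set] covering every gas/aqueous species
#'   of the reaction other than `H+`.
#' @return The reaction quotient (positive scalar). May overflow to `Inf`
#'   for extreme activities; [delta_g_prime()] works on the log scale and
#'   does not.
#' @export
reaction_quotient <- function(reaction, conditions) {
  exp(.ln_reaction_quotient(reaction, conditions))
}

.ln_reaction_quotient <- function(reaction, conditions, skip = character()) {
  stopifnot(inherits(reaction, "reaction"), inherits(conditions, "condition_set"))
  lnq <- 0
  nu <- reaction$num / reaction$den
  for (i in seq_along(reaction$species)) {
    sp <- reaction$species[i]
    if (sp %in% skip) next
    if (reaction$phase[i] %in% c("water", "solid")) next
    if (sp == "H+") {
      # relative to the pH-7 standard state
      lnq <- lnq + nu[i] * log(10) * (.PH_STANDARD - conditions$pH)
      next
    }
    a <- conditions$activities[sp]
    if (is.na(a)) {
      stop("no activity supplied for species: ", sp)
    }
    lnq <- lnq + nu[i] * log(unname(a))
  }
  lnq
}
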
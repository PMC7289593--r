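# Packaged reference scenario: the classical compilation of H2-consuming
# anaerobic respirations, the AOM half-process, AOM coupled to each
# electron-accepting partner, and the environmental condition sets under
# which their free energies are commonly reported.

#' Load the packaged reference scenario
#'
#' Returns the transcribed literature inputs the package reproduces:
#'
#' * `reactions$h2`: AOM plus six H2-consuming respirations
#'   (acetogenesis, methanogenesis, sulfate reduction, ferric iron
#'   reduction, nitrate reduction to nitrite, PCE dechlorination), each
#'   with its standard pH-7 free energy per mole of electron acceptor.
#' * `reactions$half_h2`: per-H2 reductive-dehalogenation steps
#'   (PCE->TCE, TCE->cDCE, 2-CP->phenol, MCB->benzene, and the
#'   dihaloelimination DCA->ethene). The PCE value is the tabulated
#'   one; the other four are back-calculated from the coupled reactions
#'   and the AOM free energy, since only their coupled forms are
#'   tabulated.
#' * `reactions$coupled`: CH4 oxidation coupled to each acceptor, as
#'   tabulated (the dihaloelimination row is kept in its tabulated form,
#'   whose water coefficient is one short of elemental balance; water
#'   activity is unity, so its energetics are unaffected).
#' * `conditions`: named [condition_set]s -- `standard` (1 M solutes,
#'   1 atm gases, pH 7, 298.15 K), `env_coupled` (the environmental
#'   concentrations used for the coupled-reaction dG' values),
#'   `env_profiles` (the subset used for dG'-vs-H2 curves), and
#'   `aom_breakpoint` (2.14 atm CH4, 20.2 mM bicarbonate).
#' * `registry`: the [species_registry] with charges and Henry constants
#'   (1.4e-5 mol m^-3 Pa^-1 for CH4, 7.8e-6 for H2).
#' * `constants`: see [syntherm_constants()].
#'
#' @return A list of class `scenario_bundle`.
#' @export
#' @examples
#' bundle <- scenario_bundle()
#' names(bundle$reactions$h2)
scenario_bundle <- function() {
  path <- function(f) system.file("extdata", f, package = "syntherm",
                                  mustWork = TRUE)
  registry <- read_species_registry(path("species.csv"))
  bundle <- list(
    reactions = list(
      h2 = read_reactions(path("reactions_h2.csv"), registry),
      half_h2 = read_reactions(path("reactions_half_h2.csv"), registry),
      coupled = read_reactions(path("reactions_coupled.csv"), registry)
    ),
    conditions = list(
      standard = read_conditions(path("conditions_standard.csv")),
      env_coupled = read_conditions(path("conditions_env_coupled.csv")),
      env_profiles = read_conditions(path("conditions_env_profiles.csv")),
      aom_breakpoint = read_conditions(path("conditions_aom_breakpoint.csv"))
    ),
    registry = registry,
    constants = syntherm_constants()
  )
  class(bundle) <- "scenario_bundle"
  bundle
}

# coupled rows whose tabulated dG' is not recovered from the stated
# equation and concentrations (documented discrepancy, excluded from
# reproduction checks). The nitrate row computes to about -522.0 kJ/mol
# CH4 against a tabulated -501.4; all other rows, including ferric iron,
# reproduce within the 0.1 kJ print precision.
.DISCREPANT_COUPLED <- "coupled_nitrate"

#' Recompute the reference tables
#'
#' Computes (never transcribes) the quantities tabulated in the
#' reference scenario from the packaged inputs:
#'
#' * `"h2_redox_dg"`: standard pH-7 free energies of the H2 reactions on
#'   the per-H2, per-acceptor and per-electron bases.
#' * `"h2_redox_e0"`: standard redox potentials E0' = -dG0'/(nF).
#' * `"aom_coupled_dg"`: free energies of the CH4-coupled reactions,
#'   standard and environmental, per CH4 / per acceptor / per electron.
#'   The row whose tabulated environmental value is known not to follow
#'   from the stated inputs (nitrate) carries
#'   `flag = "documented-discrepancy"`; its computed value is still
#'   reported.
#' * `"h2_profiles"`: dG' versus aqueous H2 concentration for the five
#'   H2-consuming respirations (per mol acceptor) and the AOM producer
#'   curve (per mol CH4), on a log grid.
#'
#' @param which Table key (see above).
#' @param bundle A [scenario_bundle()].
#' @param h2_grid Grid of H2 concentrations (M) for `"h2_profiles"`.
#' @return A data.frame; layout depends on `which`.
#' @export
#' @examples
#' reference_tables("h2_redox_e0")
reference_tables <- function(which = c("h2_redox_dg", "h2_redox_e0",
                                       "aom_coupled_dg", "h2_profiles"),
                             bundle = scenario_bundle(),
                             h2_grid = 10^seq(-12, -2, by = 0.1)) {
  which <- match.arg(which)
  switch(
    which,
    h2_redox_dg = .table_h2_dg(bundle),
    h2_redox_e0 = .table_h2_e0(bundle),
    aom_coupled_dg = .table_coupled(bundle),
    h2_profiles = .table_profiles(bundle, h2_grid)
  )
}

.table_h2_dg <- function(bundle) {
  rows <- lapply(bundle$reactions$h2, function(r) {
    res <- delta_g_prime(r, bundle$conditions$standard)
    nu <- coef(r)
    per_h2 <- res$dg0_prime[["per_reaction"]] / abs(nu[["H2"]])
    per_ea <- if (is.null(r$electron_acceptor)) {
      res$dg0_prime[["per_reference"]]
    } else {
      res$dg0_prime[["per_acceptor"]]
    }
    data.frame(id = r$id,
               dg0_per_h2 = per_h2,
               dg0_per_acceptor = per_ea,
               dg0_per_electron = res$dg0_prime[["per_electron"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.table_h2_e0 <- function(bundle) {
  out <- data.frame(
    id = names(bundle$reactions$h2),
    e0_volts = vapply(bundle$reactions$h2, redox_potential, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.table_coupled <- function(bundle) {
  env <- bundle$conditions$env_coupled
  rows <- lapply(bundle$reactions$coupled, function(r) {
    res <- delta_g_prime(r, env)
    data.frame(
      id = r$id,
      dg0_per_ch4 = res$dg0_prime[["per_reference"]],
      dg0_per_acceptor = res$dg0_prime[["per_acceptor"]],
      dg0_per_electron = res$dg0_prime[["per_electron"]],
      dg_prime_per_ch4 = res$dg_prime[["per_reference"]],
      dg_prime_per_acceptor = res$dg_prime[["per_acceptor"]],
      dg_prime_per_electron = res$dg_prime[["per_electron"]],
      flag = if (r$id %in% .DISCREPANT_COUPLED) "documented-discrepancy" else "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.table_profiles <- function(bundle, h2_grid) {
  env <- bundle$conditions$env_profiles
  consumers <- c("methanogenesis", "sulfate_reduction", "iron_reduction",
                 "nitrate_reduction", "pce_to_tce")
  k_h <- bundle$constants$henry_h2
  parts <- lapply(consumers, function(idname) {
    r <- bundle$reactions$h2[[idname]]
    cv <- profile_curve(r, env, h2_grid, basis = "per_acceptor", k_h = k_h)
    cbind(id = idname, cv, stringsAsFactors = FALSE)
  })
  aom <- bundle$reactions$h2[["aom"]]
  cv <- profile_curve(aom, env, h2_grid, basis = "per_reference", k_h = k_h)
  parts <- c(parts, list(cbind(id = "aom", cv, stringsAsFactors = FALSE)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
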
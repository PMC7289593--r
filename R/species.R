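#' Build a species registry
#'
#' A species registry is a data frame with one row per chemical species:
#' its name (charge encoded as a trailing `+n`/`-n` suffix, e.g. `SO4-2`,
#' `H+`, `HCO3-`), phase (`gas`, `aqueous`, `solid` or `water`), formal
#' charge in elementary units, and an optional Henry's law constant in
#' mol m^-3 Pa^-1 for gases.
#'
#' Water and solid-phase species always carry activity 1 in any condition
#' set; a Henry constant is only meaningful for gas-phase species.
#'
#' @param name Character vector of unique species names.
#' @param phase Character vector, one of `"gas"`, `"aqueous"`, `"solid"`,
#'   `"water"` (short tags `g`, `aq`, `s`, `w` are accepted).
#' @param charge Integer charges; `NA` means unknown. Defaults to the
#'   charge parsed from the trailing name suffix (0 when no suffix).
#' @param henry_mol_m3_Pa Optional Henry constants; `NA` for non-gases.
#' @return A `data.frame` of class `species_registry`.
#' @export
#' @examples
#' species_registry(c("H2", "SO4-2", "H2O"), c("g", "aq", "w"))
species_registry <- function(name, phase, charge = NULL, henry_mol_m3_Pa = NULL) {
  stopifnot(is.character(name), length(name) > 0)
  if (anyDuplicated(name)) {
    stop("duplicate species name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  phase <- .normalize_phase(phase)
  phase <- rep_len(phase, length(name))
  if (is.null(charge)) charge <- vapply(name, .charge_from_name, numeric(1))
  charge <- rep_len(as.numeric(charge), length(name))
  if (is.null(henry_mol_m3_Pa)) henry_mol_m3_Pa <- rep(NA_real_, length(name))
  henry_mol_m3_Pa <- rep_len(as.numeric(henry_mol_m3_Pa), length(name))
  bad_henry <- !is.na(henry_mol_m3_Pa) & phase != "gas"
  if (any(bad_henry)) {
    stop("Henry constant supplied for non-gas species: ",
         paste(name[bad_henry], collapse = ", "))
  }
  out <- data.frame(
    name = name, phase = phase, charge = charge,
    henry_mol_m3_Pa = henry_mol_m3_Pa,
    stringsAsFactors = FALSE
  )
  class(out) <- c("species_registry", "data.frame")
  out
}

.PHASES_LONG <- c(g = "gas", aq = "aqueous", s = "solid", w = "water")

.normalize_phase <- function(phase) {
  phase <- as.character(phase)
  short <- phase %in% names(.PHASES_LONG)
  phase[short] <- .PHASES_LONG[phase[short]]
  bad <- !phase %in% .PHASES_LONG
  if (any(bad)) stop("unknown phase: ", paste(unique(phase[bad]), collapse = ", "))
  phase
}

.phase_tag <- function(phase) names(.PHASES_LONG)[match(phase, .PHASES_LONG)]

# charge from a trailing "+n"/"-n"/"+"/"-" suffix; 0 when absent
.charge_from_name <- function(name) {
  m <- regmatches(name, regexpr("[+-][0-9]*$", name))
  if (length(m) == 0 || m == "") return(0)
  sign <- if (substr(m, 1, 1) == "+") 1 else -1
  digits <- substring(m, 2)
  sign * if (nzchar(digits)) as.numeric(digits) else 1
}

#' Read / write a species registry CSV
#'
#' The CSV has columns `name,phase,charge,henry_mol_m3_Pa`.
#'
#' @param path File path.
#' @return `read_species_registry()` returns a [species_registry];
#'   `write_species_registry()` returns `path` invisibly.
#' @export
read_species_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "phase")
  if (!all(need %in% names(df))) {
    stop("species registry CSV must have columns name, phase: ", path)
  }
  species_registry(
    name = as.character(df$name),
    phase = df$phase,
    charge = if ("charge" %in% names(df)) df$charge else NULL,
    henry_mol_m3_Pa = if ("henry_mol_m3_Pa" %in% names(df)) df$henry_mol_m3_Pa else NULL
  )
}

#' @rdname read_species_registry
#' @param registry A [species_registry].
#' @export
write_species_registry <- function(registry, path) {
  stopifnot(inherits(registry, "species_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

.registry_lookup <- function(registry, names) {
  idx <- match(names, registry$name)
  if (anyNA(idx)) {
    stop("unknown species name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  }
  registry[idx, , drop = FALSE]
}
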
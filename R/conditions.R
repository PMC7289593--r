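#' Define an environmental condition set
#'
#' A condition set assigns activities (effective concentrations) to
#' chemical species: molar concentration for aqueous solutes, partial
#' pressure in atmospheres for gases, and exactly 1 for water and solids.
#' The proton activity is not listed explicitly; it is derived from `pH`
#' and enters reaction quotients relative to the pH-7 standard state (see
#' [reaction_quotient()]). Activity coefficients are not modelled:
#' activities are taken to approximate concentrations.
#'
#' @param activities Named numeric vector of strictly positive activities.
#' @param temperature Temperature in kelvin (default 298.15 K).
#' @param pH pH of the medium (default 7).
#' @return An object of class `condition_set`.
#' @export
#' @examples
#' condition_set(c(`SO4-2` = 5.2e-3, `H2S` = 8e-4, `CH4` = 3e-5))
condition_set <- function(activities = numeric(), temperature = 298.15, pH = 7) {
  activities <- unlist(activities)
  if (length(activities) > 0) {
    if (is.null(names(activities)) || any(!nzchar(names(activities)))) {
      stop("activities must be a named vector")
    }
    if (anyDuplicated(names(activities))) {
      stop("duplicate species in activities: ",
           paste(unique(names(activities)[duplicated(names(activities))]),
                 collapse = ", "))
    }
    if (any(!is.finite(activities)) || any(activities <= 0)) {
      stop("all activities must be strictly positive and finite")
    }
  }
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  stopifnot(is.numeric(pH), length(pH) == 1, is.finite(pH))
  structure(
    list(activities = activities, temperature = temperature, pH = pH),
    class = "condition_set"
  )
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("<condition_set> T = %.2f K, pH = %g, %d species\n",
              x$temperature, x$pH, length(x$activities)))
  if (length(x$activities) > 0) {
    df <- data.frame(species = names(x$activities),
                     activity = unname(x$activities))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Look up or override a single activity
#'
#' @param conditions A [condition_set].
#' @param species Species name.
#' @param value New activity value.
#' @return `set_activity()` returns a modified copy of `conditions`.
#' @export
set_activity <- function(conditions, species, value) {
  stopifnot(inherits(conditions, "condition_set"))
  a <- conditions$activities
  a[species] <- value
  condition_set(a, conditions$temperature, conditions$pH)
}

#' Read / write a condition set CSV
#'
#' The CSV has columns `species,activity,unit` where unit is `M` for
#' aqueous solutes, `atm` for gases and `unitless` for water/solids. Two
#' reserved species rows carry the scalar state: `pH` (unit `unitless`)
#' and `temperature` (unit `K`); both are optional and default to 7 and
#' 298.15 K.
#'
#' @param path File path.
#' @return `read_conditions()` returns a [condition_set].
#' @export
read_conditions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "activity")
  if (!all(need %in% names(df))) {
    stop("condition CSV must have columns species, activity: ", path)
  }
  pH <- 7
  temperature <- 298.15
  is_ph <- df$species == "pH"
  is_temp <- df$species == "temperature"
  if (any(is_ph)) pH <- as.numeric(df$activity[is_ph][1])
  if (any(is_temp)) temperature <- as.numeric(df$activity[is_temp][1])
  df <- df[!(is_ph | is_temp), , drop = FALSE]
  acts <- as.numeric(df$activity)
  names(acts) <- df$species
  condition_set(acts, temperature = temperature, pH = pH)
}

#' @rdname read_conditions
#' @param conditions A [condition_set].
#' @param registry Optional [species_registry] used to fill the unit
#'   column; without it the unit is left blank.
#' @export
write_conditions <- function(conditions, path, registry = NULL) {
  stopifnot(inherits(conditions, "condition_set"))
  unit <- rep("", length(conditions$activities))
  if (!is.null(registry)) {
    idx <- match(names(conditions$activities), registry$name)
    unit <- c(gas = "atm", aqueous = "M", solid = "unitless",
              water = "unitless")[registry$phase[idx]]
    unit[is.na(unit)] <- ""
  }
  df <- data.frame(
    species = c(names(conditions$activities), "pH", "temperature"),
    activity = c(unname(conditions$activities), conditions$pH,
                 conditions$temperature),
    unit = c(unit, "unitless", "K"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
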
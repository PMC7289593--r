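# Reaction equation mini-grammar.
#
#   [coef] name(phase) { + [coef] name(phase) } -> [coef] name(phase) ...
#
# Coefficients are decimal ("0.5") or rational ("1/2") and must be
# separated from the species name by whitespace (names may start with a
# digit, e.g. "2-CP"). Phase tags: g, aq, s, w. Charge is encoded as a
# trailing "+n"/"-n" suffix of the name ("SO4-2", "H+", "Cl-").

#' Parse a reaction equation string
#'
#' Parses the package's equation mini-grammar into a signed stoichiometry
#' (reactants negative, products positive) plus phases and charges.
#'
#' @param text Equation string, e.g.
#'   `"CH4(g) + 2 H2O(w) -> CO2(g) + 4 H2(g)"`.
#' @return A data.frame with columns `species`, `phase`, `charge`, `num`,
#'   `den` (exact rational coefficient `num/den`, signed).
#' @export
#' @examples
#' parse_equation("SO4-2(aq) + 4 H2(g) + 2 H+(aq) -> H2S(aq) + 4 H2O(w)")
parse_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop("equation must contain exactly one '->': ", text)
  }
  lhs <- .parse_side(sides[1], text, offset = 0)
  rhs <- .parse_side(sides[2], text, offset = nchar(sides[1]) + 2)
  lhs$num <- -lhs$num
  out <- rbind(lhs, rhs)
  for (side in list(lhs$species, rhs$species)) {
    if (anyDuplicated(side)) {
      stop("duplicate species on one side of equation: ",
           paste(unique(side[duplicated(side)]), collapse = ", "))
    }
  }
  both <- intersect(lhs$species, rhs$species)
  if (length(both) > 0) {
    stop("species appear on both sides of equation (null reaction): ",
         paste(both, collapse = ", "))
  }
  out
}

.parse_side <- function(side, full_text, offset) {
  # split on "+" surrounded by whitespace so "H+(aq)" survives
  tokens <- strsplit(side, "[[:space:]]+\\+[[:space:]]+")[[1]]
  tokens_trim <- trimws(tokens)
  if (length(tokens_trim) == 0 || any(!nzchar(tokens_trim))) {
    stop("empty species term in equation: ", full_text)
  }
  pos <- offset
  rows <- vector("list", length(tokens_trim))
  for (i in seq_along(tokens_trim)) {
    tok <- tokens_trim[i]
    at <- offset + regexpr(tok, side, fixed = TRUE)[1]
    rows[[i]] <- .parse_term(tok, at)
    pos <- at + nchar(tok)
  }
  do.call(rbind, rows)
}

.parse_term <- function(token, at) {
  m <- regexec("^(?:([0-9]+(?:\\.[0-9]+)?|[0-9]+/[0-9]+)[[:space:]]+)?(.+)\\(([A-Za-z]+)\\)$",
               token)
  g <- regmatches(token, m)[[1]]
  if (length(g) == 0) {
    stop(sprintf("malformed species term '%s' at character %d (expected '[coef] name(phase)')",
                 token, at))
  }
  coef_txt <- g[2]
  name <- g[3]
  phase_tag <- g[4]
  if (grepl("[[:space:]]", name)) {
    stop(sprintf("malformed species term '%s' at character %d (missing '+' between species?)",
                 token, at))
  }
  if (!phase_tag %in% names(.PHASES_LONG)) {
    stop(sprintf("unknown phase tag '(%s)' in term '%s' at character %d",
                 phase_tag, token, at))
  }
  if (!nzchar(coef_txt)) {
    num <- 1; den <- 1
  } else {
    r <- .rationalize(coef_txt)
    num <- r$num; den <- r$den
  }
  if (num == 0) {
    stop(sprintf("zero coefficient in term '%s' at character %d", token, at))
  }
  data.frame(
    species = name,
    phase = .PHASES_LONG[[phase_tag]],
    charge = .charge_from_name(name),
    num = num, den = den,
    stringsAsFactors = FALSE
  )
}

.format_coef <- function(num, den) {
  if (den == 1) {
    if (num == round(num)) {
      if (num == 1) "" else paste0(format(num, scientific = FALSE), " ")
    } else {
      paste0(format(num, digits = 15), " ")
    }
  } else {
    paste0(format(num, scientific = FALSE), "/",
           format(den, scientific = FALSE), " ")
  }
}

#' Write a reaction as a canonical equation string
#'
#' The inverse of [parse_equation()]: species are emitted reactants
#' first, each side sorted alphabetically by name, with `1` coefficients
#' omitted and rational coefficients as `p/q`. Parsing the output
#' recovers the same stoichiometry; writing it again is byte-identical.
#'
#' @param reaction A [reaction] object.
#' @return A single equation string.
#' @export
format_equation <- function(reaction) {
  stopifnot(inherits(reaction, "reaction"))
  fmt_side <- function(idx) {
    idx <- idx[order(reaction$species[idx])]
    paste(vapply(idx, function(i) {
      paste0(.format_coef(abs(reaction$num[i]), reaction$den[i]),
             reaction$species[i], "(", .phase_tag(reaction$phase[i]), ")")
    }, character(1)), collapse = " + ")
  }
  lhs <- which(reaction$num < 0)
  rhs <- which(reaction$num > 0)
  if (length(lhs) == 0 || length(rhs) == 0) {
    stop("cannot format a one-sided or empty reaction")
  }
  paste(fmt_side(lhs), "->", fmt_side(rhs))
}
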
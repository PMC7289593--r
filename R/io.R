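#' Read / write a reaction table CSV
#'
#' The CSV has columns
#' `id,equation,dg0_prime_kj,ref_species,donor,acceptor,n_electrons`.
#' The equation column uses the mini-grammar of [parse_equation()];
#' `dg0_prime_kj` is kJ per mol of `ref_species`; empty `donor`/
#' `acceptor`/`n_electrons` cells mean "not designated".
#'
#' @param path File path.
#' @param registry Optional [species_registry]; when given, every species
#'   must exist in it and each reaction is checked with
#'   [validate_reaction()] (violations raise a warning).
#' @return `read_reactions()` returns a named list of [reaction] objects.
#' @export
read_reactions <- function(path, registry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "equation", "dg0_prime_kj", "ref_species")
  if (!all(need %in% names(df))) {
    stop("reaction CSV must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  blank_to_null <- function(x) if (is.na(x) || !nzchar(x)) NULL else x
  out <- lapply(seq_len(nrow(df)), function(i) {
    n_e <- if ("n_electrons" %in% names(df)) df$n_electrons[i] else ""
    r <- reaction(
      id = df$id[i],
      equation = df$equation[i],
      dg0_prime = as.numeric(df$dg0_prime_kj[i]),
      reference_species = blank_to_null(df$ref_species[i]),
      electron_donor = blank_to_null(if ("donor" %in% names(df)) df$donor[i] else ""),
      electron_acceptor = blank_to_null(if ("acceptor" %in% names(df)) df$acceptor[i] else ""),
      n_electrons = if (is.null(blank_to_null(n_e))) NA_real_ else as.numeric(n_e)
    )
    if (!is.null(registry)) {
      v <- validate_reaction(r, registry)
      if (length(v) > 0) {
        warning(sprintf("reaction '%s': %s", r$id, paste(v, collapse = "; ")))
      }
    }
    r
  })
  stats::setNames(out, df$id)
}

#' @rdname read_reactions
#' @param reactions A list of [reaction] objects.
#' @export
write_reactions <- function(reactions, path) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  df <- do.call(rbind, lapply(reactions, function(r) {
    data.frame(
      id = r$id,
      equation = format_equation(r),
      dg0_prime_kj = r$dg0_prime,
      ref_species = r$reference_species %||% "",
      donor = r$electron_donor %||% "",
      acceptor = r$electron_acceptor %||% "",
      n_electrons = if (is.na(r$n_electrons)) "" else r$n_electrons,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
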
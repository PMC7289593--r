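# Exact rational arithmetic on stoichiometric coefficients.
#
# Coefficients are stored as numerator/denominator pairs of doubles that
# hold exact integer values (safe well below 2^53 for any realistic
# stoichiometry), so scaling and coupling of reactions introduce no
# floating-point drift. A coefficient that cannot be rationalised (e.g. a
# coupling weight like pi) degrades to num = value, den = 1 and is marked
# inexact by the caller.

.gcd2 <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (b > 0.5) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  if (a < 0.5) 1 else a
}

# reduce num/den to lowest terms with positive denominator
.rat_reduce <- function(num, den) {
  stopifnot(length(num) == length(den), all(den != 0))
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  integral <- num == round(num) & den == round(den)
  g <- rep(1, length(num))
  g[integral] <- mapply(.gcd2, num[integral], den[integral])
  list(num = num / g, den = den / g)
}

.rat_add <- function(n1, d1, n2, d2) .rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
.rat_mul <- function(n1, d1, n2, d2) .rat_reduce(n1 * n2, d1 * d2)

# continued-fraction rationalisation of a numeric scalar; returns
# list(num, den, exact). Strings "p/q" are parsed exactly.
.rationalize <- function(x, max_den = 1e9, tol = 1e-12) {
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("^-?[0-9]+/[0-9]+$", x)) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1]]
      r <- .rat_reduce(as.numeric(parts[1]), as.numeric(parts[2]))
      return(list(num = r$num, den = r$den, exact = TRUE))
    }
    x <- as.numeric(x)
  }
  stopifnot(is.numeric(x), length(x) == 1, is.finite(x))
  if (x == round(x)) {
    return(list(num = x, den = 1, exact = TRUE))
  }
  # continued fraction expansion
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  for (i in seq_len(64)) {
    a <- floor(b)
    h2 <- a * h1 + h0
    k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x) <= tol * max(1, abs(x))) {
      r <- .rat_reduce(h1, k1)
      return(list(num = r$num, den = r$den, exact = TRUE))
    }
    frac <- b - a
    if (frac < 1e-15) break
    b <- 1 / frac
  }
  list(num = x, den = 1, exact = FALSE)
}
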
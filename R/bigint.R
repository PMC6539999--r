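# Minimal arbitrary-precision non-negative integers for exact library
# diversity arithmetic.  Representation: integer vector of base-1e4 digits,
# little-endian.  Only the operations the library module needs are provided:
# construction, multiplication by a machine integer, product, power, log10,
# decimal rendering and numeric coercion.

EXACT_BASE <- 10000L

#' Exact non-negative integer
#'
#' @param x A non-negative integral numeric (at most 2^53), a decimal digit
#'   string, or an `exactint`.
#' @return An object of class `exactint`.
#' @export
as_exactint <- function(x) {
  if (inherits(x, "exactint")) return(x)
  if (is.character(x)) {
    x <- gsub("[ ,]", "", x)
    if (!grepl("^[0-9]+$", x)) stop("not a decimal integer string: ", x)
    n <- nchar(x)
    starts <- rev(seq(n, 1L, by = -4L))
    digs <- rev(vapply(starts, function(s) {
      as.integer(substr(x, max(1L, s - 3L), s))
    }, integer(1)))
    return(exact_trim(digs))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x) || x > 2^53) {
    stop("as_exactint needs a single non-negative integral value <= 2^53")
  }
  digs <- integer()
  x <- as.numeric(x)
  repeat {
    digs <- c(digs, as.integer(x %% EXACT_BASE))
    x <- floor(x / EXACT_BASE)
    if (x == 0) break
  }
  exact_trim(digs)
}

exact_trim <- function(digs) {
  while (length(digs) > 1L && digs[length(digs)] == 0L) {
    digs <- digs[-length(digs)]
  }
  structure(digs, class = "exactint")
}

# multiply by a machine integer 0 <= m < 2^20
exact_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m))
  if (m == 0) return(as_exactint(0))
  digs <- as.numeric(unclass(a)) * m
  carry <- 0
  out <- numeric(0)
  for (i in seq_along(digs)) {
    v <- digs[i] + carry
    out[i] <- v %% EXACT_BASE
    carry <- floor(v / EXACT_BASE)
  }
  while (carry > 0) {
    out <- c(out, carry %% EXACT_BASE)
    carry <- floor(carry / EXACT_BASE)
  }
  exact_trim(as.integer(out))
}

#' Exact product of a vector of machine integers
#'
#' @param sizes Non-negative integers (e.g. per-position identity-set sizes).
#' @return An `exactint`; the empty product is 1.
#' @export
exact_product <- function(sizes) {
  acc <- as_exactint(1)
  for (s in sizes) acc <- exact_mul_small(acc, s)
  acc
}

#' Exact integer power
#'
#' @param base,exponent Non-negative machine integers.
#' @return An `exactint` equal to `base ^ exponent`.
#' @export
exact_pow <- function(base, exponent) {
  stopifnot(exponent >= 0, exponent == floor(exponent))
  exact_product(rep(base, exponent))
}

#' @export
as.character.exactint <- function(x, ...) {
  digs <- rev(unclass(x))
  paste0(digs[1L], paste(sprintf("%04d", digs[-1L]), collapse = ""))
}

#' @export
format.exactint <- function(x, ...) as.character(x)

#' @export
print.exactint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
as.double.exactint <- function(x, ...) {
  s <- as.character(x)
  if (nchar(s) <= 15L) return(as.numeric(s))
  lead <- as.numeric(substr(s, 1L, 15L))
  lead * 10^(nchar(s) - 15L)
}

#' Base-10 logarithm of an exact integer
#'
#' Computed from the decimal expansion, so it stays accurate far beyond the
#' double-precision integer range.
#'
#' @param x An `exactint` (or any positive numeric).
#' @return `log10(x)` as a double.
#' @export
exact_log10 <- function(x) {
  if (!inherits(x, "exactint")) {
    stopifnot(is.numeric(x), x > 0)
    return(log10(as.numeric(x)))
  }
  s <- as.character(x)
  if (s == "0") stop("log10 of zero")
  lead <- as.numeric(substr(s, 1L, min(15L, nchar(s))))
  (nchar(s) - min(15L, nchar(s))) + log10(lead)
}

#' Scientific-notation rendering at a given number of significant figures
#'
#' Renders the way diversity numbers are usually quoted, e.g.
#' `"1.6e+08"` for 159,252,480 at 2 significant figures.
#'
#' @param x An `exactint` or positive numeric.
#' @param sig Significant figures (default 2).
#' @return Character scalar.
#' @export
format_sci <- function(x, sig = 2) {
  lg <- exact_log10(x)
  e <- floor(lg)
  mant <- round(10^(lg - e), sig - 1L)
  if (mant >= 10) {
    mant <- mant / 10
    e <- e + 1
  }
  sprintf("%.*fe%+03d", sig - 1L, mant, e)
}

#' @export
`==.exactint` <- function(e1, e2) {
  as.character(as_exactint(e1)) == as.character(as_exactint(e2))
}
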
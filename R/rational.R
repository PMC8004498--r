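# ---------------------------------------------------------------------------
# Minimal exact rational arithmetic.
#
# Probabilities in worked examples are exact fractions (1/2, 1/10, 2/5, ...);
# the quantities derived from the recombination distribution alone (marginal
# recombination probabilities, sojourn probabilities, entries of the
# unlabelled transition matrix) are computed exactly in this representation
# when the model carries exact weights.  Numerators and denominators are
# stored as doubles but kept integral; all values arising here are far below
# 2^53, so arithmetic is exact.
# ---------------------------------------------------------------------------

rat_gcd <- function(a, b) {
  mapply(function(x, y) {
    x <- abs(x); y <- abs(y)
    while (y != 0) { t <- y; y <- x %% y; x <- t }
    x
  }, a, b)
}

#' Exact rational numbers
#'
#' Construct a vector of exact rationals from integral numerators and
#' denominators (reduced to lowest terms, denominator positive).  Used for
#' the exact-arithmetic mode of recombination-derived probabilities.
#'
#' @param num,den numeric vectors of integral values; `den` must be non-zero.
#' @return An object of class `rational` with fields `num` and `den`.
#' @examples
#' rational(2, 5) + rational(1, 10)
#' @export
rational <- function(num, den = 1) {
  stopifnot(all(den != 0), all(num == round(num)), all(den == round(den)))
  k <- max(length(num), length(den))
  num <- rep_len(num, k); den <- rep_len(den, k)
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn; den <- den * sgn
  g <- rat_gcd(num, den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num), sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    stop("unsupported unary operation for rational: ", .Generic, call. = FALSE)
  }
  if (!inherits(e1, "rational")) e1 <- rational(e1)
  if (!inherits(e2, "rational")) e2 <- rational(e2)
  switch(.Generic,
    "+" = rational(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den),
    "-" = rational(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den),
    "*" = rational(e1$num * e2$num, e1$den * e2$den),
    "/" = rational(e1$num * e2$den, e1$den * e2$num),
    "==" = e1$num * e2$den == e2$num * e1$den,
    "!=" = e1$num * e2$den != e2$num * e1$den,
    "<"  = e1$num * e2$den < e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den > e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop("unsupported operation for rational: ", .Generic, call. = FALSE)
  )
}

rat_sum <- function(x) {
  out <- rational(0)
  for (i in seq_along(x$num)) out <- out + x[i]
  out
}

rat_prod <- function(xs) {
  out <- rational(1)
  for (x in xs) out <- out * x
  out
}

#' Parse fractions from text
#'
#' Accepts strings like `"2/5"` or `"0.4"`-free integer forms like `"3"`;
#' plain numerics are accepted when integral over a power-of-ten denominator
#' is not required (they must be exactly representable ratios entered as
#' strings to be treated exactly).
#'
#' @param x character vector of fractions `"p/q"` or integers.
#' @return A `rational` vector.
#' @export
parse_rational <- function(x) {
  x <- as.character(x)
  num <- numeric(length(x)); den <- numeric(length(x))
  for (i in seq_along(x)) {
    parts <- strsplit(trimws(x[i]), "/", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      num[i] <- as.numeric(parts[1]); den[i] <- 1
    } else if (length(parts) == 2) {
      num[i] <- as.numeric(parts[1]); den[i] <- as.numeric(parts[2])
    } else stop("cannot parse rational: ", x[i], call. = FALSE)
    if (num[i] != round(num[i]) || den[i] != round(den[i]))
      stop("rational parts must be integers: ", x[i], call. = FALSE)
  }
  rational(num, den)
}
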
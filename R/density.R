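#' Exact rational graph density
#'
#' Density of a graph is the ratio |E|/|V|. Solvers compare densities of
#' candidate subgraphs by exact integer cross-multiplication, never through
#' floating point, so that stopping rules (Min-DS / Min-SDS peeling) cannot
#' be perturbed by LP round-off. Counts stay far below 2^53, so products of
#' two or three of them are exact in double arithmetic.
#'
#' @param num edge count (non-negative integer)
#' @param den vertex count (positive integer)
#' @return an object of class `rho` with fields `num`, `den`
#' @examples
#' rho(6, 4)           # density of K4
#' rho_value(rho(6, 4))
#' @export
rho <- function(num, den) {
  num <- as.numeric(num); den <- as.numeric(den)
  if (length(num) != 1L || length(den) != 1L || is.na(num) || is.na(den) ||
      num < 0 || den < 1 || num != floor(num) || den != floor(den)) {
    abort_input("density requires integer numerator >= 0 and denominator >= 1")
  }
  structure(list(num = num, den = den), class = "rho")
}

#' @rdname rho
#' @param x a `rho` object
#' @export
rho_value <- function(x) x$num / x$den

#' Compare two exact densities
#'
#' @param a,b `rho` objects
#' @return -1, 0 or 1 as `a` is less than, equal to, or greater than `b`
#' @export
rho_cmp <- function(a, b) {
  stopifnot(inherits(a, "rho"), inherits(b, "rho"))
  sign(a$num * b$den - b$num * a$den)
}

#' Compare a density against theta * D for a decimal tolerance theta
#'
#' theta is held as an exact decimal fraction a/10^k (k <= 9 digits), so the
#' comparison rho < theta * D is an exact integer comparison:
#' num * Dden * 10^k  vs  a * Dnum * den.
#'
#' @param r candidate density (`rho`)
#' @param theta numeric scalar in (0, 1), interpreted at its printed decimal
#' @param D reference maximum density (`rho`)
#' @return -1, 0, 1 as r is less than, equal to, greater than theta * D
#' @export
rho_cmp_scaled <- function(r, theta, D) {
  stopifnot(inherits(r, "rho"), inherits(D, "rho"))
  tf <- theta_fraction(theta)
  sign(r$num * D$den * tf$den - tf$num * D$num * r$den)
}

# exact decimal representation of a tolerance like 0.85 -> 85/100
theta_fraction <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta)) {
    abort_input("theta must be a numeric scalar")
  }
  for (k in 0:9) {
    a <- theta * 10^k
    if (abs(a - round(a)) < 1e-9 * max(1, abs(a))) {
      return(list(num = round(a), den = 10^k))
    }
  }
  # irrational-ish theta (e.g. 1 - 1e-12): fall back to a 12-digit decimal
  list(num = round(theta * 1e12), den = 1e12)
}

#' @export
format.rho <- function(x, ...) {
  sprintf("%s/%s (%.6g)", format(x$num, scientific = FALSE),
          format(x$den, scientific = FALSE), x$num / x$den)
}

#' @export
print.rho <- function(x, ...) {
  cat("density", format(x), "\n")
  invisible(x)
}
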
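# Exact integer / rational helpers underlying the flux algebra.
#
# All stoichiometric coefficients are small rationals; internally every
# computation is reduced to integer arithmetic stored in doubles (exact up to
# 2^53). Overflow is guarded, not silently tolerated.

.INT_GUARD <- 2^49

.chk_int_range <- function(x) {
  if (any(abs(x) > .INT_GUARD)) {
    stop("exact integer arithmetic overflow guard exceeded; ",
         "coefficients grew beyond 2^49", call. = FALSE)
  }
  x
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(0)
  g <- x[1]
  for (v in x[-1]) {
    g <- gcd2(g, v)
    if (g == 1) break
  }
  g
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

#' Rational approximation of a numeric scalar
#'
#' Continued-fraction expansion, used to recover exact small rationals from
#' numeric input (e.g. 0.5 -> 1/2). Coefficients in network definitions are
#' expected to be ratios of small integers.
#'
#' @param x numeric scalar.
#' @param max_den largest admissible denominator.
#' @return integer vector c(numerator, denominator), denominator > 0.
#' @keywords internal
as_rational <- function(x, max_den = 1e6) {
  if (!is.finite(x)) stop("non-finite coefficient", call. = FALSE)
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  # continued fraction convergents
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  a <- x
  repeat {
    ai <- floor(a)
    p2 <- ai * p1 + p0
    q2 <- ai * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12 * max(1, x)) break
    frac <- a - ai
    if (frac < 1e-12) break
    a <- 1 / frac
  }
  if (abs(p1 / q1 - x) > 1e-9 * max(1, x)) {
    stop("coefficient ", sign * x, " is not a small rational", call. = FALSE)
  }
  c(sign * p1, q1)
}

# Scale a numeric vector of small rationals to coprime integers.
# Returns the integer vector; errors if entries are not small rationals.
to_coprime_integers <- function(v) {
  nz <- v != 0
  if (!any(nz)) return(v)
  rats <- vapply(v[nz], as_rational, numeric(2))
  den_lcm <- 1
  for (d in rats[2, ]) den_lcm <- lcm2(den_lcm, d)
  ints <- v
  ints[nz] <- rats[1, ] * (den_lcm / rats[2, ])
  .chk_int_range(ints)
  g <- gcd_vec(ints)
  if (g > 1) ints <- ints / g
  ints
}

# Clear denominators row-wise: each row of a rational matrix is scaled by the
# lcm of its denominators (row scaling leaves the nullspace unchanged).
integerize_rows <- function(M) {
  if (nrow(M) == 0L) return(M)
  for (i in seq_len(nrow(M))) {
    r <- M[i, ]
    if (any(r != round(r))) {
      M[i, ] <- to_coprime_integers(r)
    }
  }
  M
}

#' Exact rank of an integer matrix
#'
#' Fraction-free (Bareiss) Gaussian elimination; division-free correctness,
#' exact for integer entries within the double-precision integer range.
#'
#' @param A numeric matrix with integer entries.
#' @return integer rank.
#' @keywords internal
int_rank <- function(A) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L || n == 0L) return(0L)
  A <- matrix(as.numeric(A), m, n)
  prev <- 1
  r <- 0L
  col <- 1L
  while (r < m && col <= n) {
    piv_rows <- which(A[(r + 1L):m, col] != 0) + r
    if (length(piv_rows) == 0L) {
      col <- col + 1L
      next
    }
    # smallest pivot magnitude limits coefficient growth
    p <- piv_rows[which.min(abs(A[piv_rows, col]))]
    r <- r + 1L
    if (p != r) A[c(p, r), ] <- A[c(r, p), ]
    if (r < m) {
      rows <- (r + 1L):m
      piv <- A[r, col]
      A[rows, ] <- (A[rows, ] * piv -
                      outer(A[rows, col], A[r, ])) / prev
      .chk_int_range(A[rows, ])
    }
    prev <- A[r, col]
    col <- col + 1L
  }
  r
}

#' Exact determinant of a square integer matrix (Bareiss)
#' @keywords internal
int_det <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(1)
  if (n != ncol(A)) stop("determinant of non-square matrix", call. = FALSE)
  A <- matrix(as.numeric(A), n, n)
  prev <- 1
  sgn <- 1
  for (k in seq_len(n - 1L)) {
    if (A[k, k] == 0) {
      p <- which(A[(k + 1L):n, k] != 0)
      if (length(p) == 0L) return(0)
      p <- p[1] + k
      A[c(p, k), ] <- A[c(k, p), ]
      sgn <- -sgn
    }
    rows <- (k + 1L):n
    A[rows, ] <- (A[rows, ] * A[k, k] -
                    outer(A[rows, k], A[k, ])) / prev
    .chk_int_range(A[rows, ])
    prev <- A[k, k]
  }
  sgn * A[n, n]
}

# One-dimensional integer kernel of an integer matrix known to have
# rank == ncol - 1. Returns a coprime integer vector, or NULL if the rank
# condition fails. Uses Cramer expansion over a maximal independent row set.
int_kernel_1d <- function(A) {
  k <- ncol(A)
  if (k == 0L) return(NULL)
  if (nrow(A) == 0L) {
    if (k == 1L) return(1)
    return(NULL)
  }
  if (int_rank(A) != k - 1L) return(NULL)
  # greedily select k-1 independent rows
  sel <- integer(0)
  for (i in seq_len(nrow(A))) {
    if (length(sel) == k - 1L) break
    cand <- c(sel, i)
    if (int_rank(A[cand, , drop = FALSE]) == length(cand)) sel <- cand
  }
  B <- A[sel, , drop = FALSE]
  v <- vapply(seq_len(k), function(j) {
    (-1)^(j + 1) * int_det(B[, -j, drop = FALSE])
  }, numeric(1))
  g <- gcd_vec(v)
  if (g > 1) v <- v / g
  v
}
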